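# Pool one subject's (alpha, omega, u) triples over their sessions,
# dropping t = 1 and excluded observations.
pool_determinants <- function(series_list, normative_traces, u_field = "u") {
  norm_map <- stats::setNames(
    normative_traces,
    vapply(normative_traces, `[[`, "", "sequence_id")
  )
  alpha <- om <- uu <- list()
  for (s in series_list) {
    nt <- norm_map[[attr(s, "sequence_id")]]
    if (is.null(nt)) stop("data error: no normative trace for sequence ",
                          attr(s, "sequence_id"), call. = FALSE)
    keep <- !s$excluded & s$t > 1L
    alpha[[length(alpha) + 1L]] <- s$alpha[keep]
    om[[length(om) + 1L]] <- nt$omega[s$t[keep]]
    uu[[length(uu) + 1L]] <- nt[[u_field]][s$t[keep]]
  }
  data.frame(alpha = unlist(alpha), omega = unlist(om), u = unlist(uu))
}

#' Two-determinant regression of the learning rate
#'
#' Regresses a subject's apparent learning rate on the two normative
#' determinants — change-point probability (omega) and prior uncertainty
#' (u) — after z-scoring all three variables within subject across all their
#' pooled observations of a task, so the two weights are commensurable.
#' Observations at t = 1 and excluded observations are dropped.
#'
#' @param series_list One subject's `lr_series` objects (a single series is
#'   accepted), all from the same task.
#' @param normative_traces Normative traces covering the series' sequences
#'   (matched by `sequence_id`).
#' @param u_field Which uncertainty to use as the regressor: `"u"` (SD of
#'   the change-point-predicted prior, the default) or `"u_prev"` (SD of the
#'   previous posterior).
#' @param min_obs Minimum number of valid observations (default 10).
#' @return A `determinant_weights` list: `w_omega`, `w_u`, `intercept`,
#'   `n`, `subject_id`, `task`.
#' @export
regress_determinants <- function(series_list, normative_traces,
                                 u_field = c("u", "u_prev"), min_obs = 10L) {
  u_field <- match.arg(u_field)
  if (inherits(series_list, "lr_series")) series_list <- list(series_list)
  d <- pool_determinants(series_list, normative_traces, u_field)
  if (nrow(d) < min_obs) {
    stop("data error: fewer than ", min_obs, " valid observations", call. = FALSE)
  }
  az <- zscore(d$alpha, "alpha")
  oz <- zscore(d$omega, "omega")
  uz <- zscore(d$u, "u")
  fit <- stats::lm(az ~ oz + uz)
  co <- stats::coef(fit)
  structure(
    list(w_omega = unname(co["oz"]), w_u = unname(co["uz"]),
         intercept = unname(co["(Intercept)"]), n = nrow(d),
         subject_id = attr(series_list[[1]], "subject_id"),
         task = attr(series_list[[1]], "task")),
    class = "determinant_weights"
  )
}

#' @export
print.determinant_weights <- function(x, ...) {
  cat(sprintf("<determinant_weights> %s, %s task (n = %d): w_omega = %.3f, w_u = %.3f\n",
              x$subject_id, x$task, x$n, x$w_omega, x$w_u))
  invisible(x)
}

#' Per-subject determinant weights for a cohort
#'
#' Groups learning-rate series by subject and runs
#' [regress_determinants()] on each.
#'
#' @inheritParams regress_determinants
#' @return Data frame with one row per subject: `subject_id`, `task`,
#'   `w_omega`, `w_u`, `intercept`, `n`.
#' @export
determinant_weights_by_subject <- function(series_list, normative_traces,
                                           u_field = "u", min_obs = 10L) {
  subj <- vapply(series_list, function(s) attr(s, "subject_id"), "")
  rows <- lapply(unique(subj), function(sid) {
    w <- regress_determinants(series_list[subj == sid], normative_traces,
                              u_field = u_field, min_obs = min_obs)
    data.frame(subject_id = sid, task = w$task, w_omega = w$w_omega,
               w_u = w$w_u, intercept = w$intercept, n = w$n)
  })
  do.call(rbind, rows)
}

#' Group-level tests of the determinant weights
#'
#' Two-tailed one-sample t-tests of each weight against zero, and a paired
#' t-test comparing the change-point-probability weight with the
#' prior-uncertainty weight across subjects (positive t means omega
#' dominates).
#'
#' @param weights Data frame from [determinant_weights_by_subject()].
#' @return A list of three test summaries (`w_omega`, `w_u`, `paired`), each
#'   with `t`, `df`, `p`, `mean`, `sem`.
#' @export
group_level_tests <- function(weights) {
  if (nrow(weights) < 2) stop("data error: need at least 2 subjects", call. = FALSE)
  one <- function(v) {
    tt <- stats::t.test(v)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean = mean(v), sem = stats::sd(v) / sqrt(length(v)))
  }
  paired <- stats::t.test(weights$w_omega, weights$w_u, paired = TRUE)
  list(
    w_omega = one(weights$w_omega),
    w_u = one(weights$w_u),
    paired = list(t = unname(paired$statistic), df = unname(paired$parameter),
                  p = paired$p.value,
                  mean = mean(weights$w_omega - weights$w_u),
                  sem = stats::sd(weights$w_omega - weights$w_u) /
                    sqrt(nrow(weights)))
  )
}

# Quantile-bin a vector into n bins (1-based labels); ties collapse bins.
quantile_bin <- function(x, n_bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Interaction pattern of the two determinants on the learning rate
#'
#' Bins each subject's observations into quantile bins of change-point
#' probability and of prior uncertainty, takes cell means of the learning
#' rate within subject, and averages the cells across subjects. The default
#' binning puts more bins along the factor with the wider variation range:
#' 4 omega x 2 u bins for the magnitude task, 2 omega x 4 u bins for the
#' probability task.
#'
#' @inheritParams regress_determinants
#' @param n_omega_bins,n_u_bins Number of quantile bins per factor; if NULL,
#'   task-dependent defaults as above.
#' @return An `interaction_grid`: `cell_means` (omega bins x u bins, NA for
#'   empty cells), `n_subjects` per cell, bin counts and task.
#' @export
interaction_pattern <- function(series_list, normative_traces,
                                n_omega_bins = NULL, n_u_bins = NULL,
                                u_field = "u") {
  subj <- vapply(series_list, function(s) attr(s, "subject_id"), "")
  task <- attr(series_list[[1]], "task")
  if (is.null(n_omega_bins)) n_omega_bins <- if (task == "magnitude") 4L else 2L
  if (is.null(n_u_bins)) n_u_bins <- if (task == "magnitude") 2L else 4L
  check_number(n_omega_bins, "n_omega_bins", 2)
  check_number(n_u_bins, "n_u_bins", 2)
  acc <- array(0, dim = c(n_omega_bins, n_u_bins))
  cnt <- acc
  for (sid in unique(subj)) {
    d <- pool_determinants(series_list[subj == sid], normative_traces, u_field)
    ob <- quantile_bin(d$omega, n_omega_bins)
    ub <- quantile_bin(d$u, n_u_bins)
    for (i in seq_len(n_omega_bins)) {
      for (j in seq_len(n_u_bins)) {
        sel <- ob == i & ub == j
        if (any(sel)) {
          acc[i, j] <- acc[i, j] + mean(d$alpha[sel])
          cnt[i, j] <- cnt[i, j] + 1L
        }
      }
    }
  }
  cell_means <- acc / cnt
  cell_means[cnt == 0] <- NA_real_
  structure(
    list(cell_means = cell_means, n_subjects = cnt,
         n_omega_bins = n_omega_bins, n_u_bins = n_u_bins, task = task),
    class = "interaction_grid"
  )
}

#' @export
print.interaction_grid <- function(x, ...) {
  cat(sprintf("<interaction_grid> %s task, %d omega bins x %d u bins\n",
              x$task, x$n_omega_bins, x$n_u_bins))
  m <- round(x$cell_means, 3)
  dimnames(m) <- list(paste0("omega", seq_len(x$n_omega_bins)),
                      paste0("u", seq_len(x$n_u_bins)))
  print(m)
  invisible(x)
}
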