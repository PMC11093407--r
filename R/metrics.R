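#' Per-observation apparent learning rates
#'
#' The apparent learning rate of observation t is the ratio of the report
#' update to the prediction error,
#' \deqn{\alpha_t = (v_t - v_{t-1}) / (x_t - v_{t-1}),}
#' a model-free measure of how much weight the learner gave the observation.
#' Observations with (near-)zero prediction error have an undefined learning
#' rate and are marked excluded. For the magnitude task, ratio outliers —
#' which occur when the error is very close to zero — outside
#' `outlier_bounds` are additionally excluded when `exclude_outliers` is set.
#'
#' @param trace An `estimate_trace` (reports `v_0:T`).
#' @param seq The matching `obs_sequence`.
#' @param exclude_outliers Apply the magnitude-task outlier rule
#'   (default TRUE; ignored for the probability task).
#' @param outlier_bounds Retained learning-rate range for the magnitude task
#'   (default c(-0.6, 1.3)).
#' @param eps Prediction errors with absolute value below `eps` count as
#'   zero (default 1e-9).
#' @return An `lr_series`: data frame with columns `t`, `alpha` (NA where
#'   excluded), `excluded`, `cp`, plus attributes `task`, `subject_id`,
#'   `sequence_id`.
#' @export
compute_learning_rates <- function(trace, seq, exclude_outliers = TRUE,
                                   outlier_bounds = c(-0.6, 1.3),
                                   eps = 1e-9) {
  stopifnot(inherits(trace, "estimate_trace"), inherits(seq, "obs_sequence"))
  if (trace$n_obs != seq$n_obs) {
    stop("data error: trace and sequence lengths differ", call. = FALSE)
  }
  T_ <- seq$n_obs
  v_prev <- trace$v[seq_len(T_)]
  v_cur <- trace$v[seq_len(T_) + 1L]
  pe <- seq$x - v_prev
  alpha <- (v_cur - v_prev) / pe
  excluded <- abs(pe) < eps
  if (exclude_outliers && trace$task == "magnitude") {
    excluded <- excluded | (!is.na(alpha) &
                              (alpha < outlier_bounds[1] | alpha > outlier_bounds[2]))
  }
  alpha[excluded] <- NA_real_
  out <- data.frame(t = seq_len(T_), alpha = alpha, excluded = excluded,
                    cp = seq$cp)
  attr(out, "task") <- trace$task
  attr(out, "subject_id") <- trace$agent_id
  attr(out, "sequence_id") <- trace$sequence_id
  class(out) <- c("lr_series", "data.frame")
  out
}

# Offsets in a window c(pre, post) around a change point; offset +1 is the
# first observation of the new regime (where cp is TRUE), offset -1 the last
# observation before it. There is no offset 0.
window_offsets <- function(window) {
  stopifnot(length(window) == 2L, window[1] <= -2, window[2] >= 1)
  c(seq(window[1], -1L), seq(1L, window[2]))
}

#' Change-point-aligned learning-rate dynamics
#'
#' Aligns per-observation learning rates to change points and averages them
#' within subject, then across subjects. For each change point, offset +k is
#' the k-th observation after the change and offset -k the k-th before it.
#' Change points without two clean (non-excluded, in-session) pre-change
#' observations are dropped. The pre-change baseline is the mean over
#' offsets -2 and -1.
#'
#' @param series_list List of `lr_series`, one per (subject, session).
#' @param window Integer pair c(pre, post), default c(-2, 8).
#' @return An `lr_dynamics` object: `offsets`, `mean_curve`, `sem_curve`,
#'   `baseline` (group mean of per-subject baselines), `subject_matrix`
#'   (subjects x offsets), `subject_baselines`, `n_subjects`.
#' @export
align_to_changepoints <- function(series_list, window = c(-2L, 8L)) {
  offs <- window_offsets(window)
  subjects <- unique(vapply(series_list, function(s) attr(s, "subject_id"), ""))
  sum_mat <- matrix(0, length(subjects), length(offs),
                    dimnames = list(subjects, offs))
  cnt_mat <- sum_mat
  for (s in series_list) {
    subj <- attr(s, "subject_id")
    T_ <- nrow(s)
    for (cp_t in which(s$cp)) {
      if (cp_t - 2L < 1L) next
      if (s$excluded[cp_t - 1L] || s$excluded[cp_t - 2L]) next
      for (j in seq_along(offs)) {
        k <- offs[j]
        t <- if (k > 0) cp_t + k - 1L else cp_t + k
        if (t < 1L || t > T_) next
        a <- s$alpha[t]
        if (is.na(a)) next
        sum_mat[subj, j] <- sum_mat[subj, j] + a
        cnt_mat[subj, j] <- cnt_mat[subj, j] + 1L
      }
    }
  }
  subj_mat <- sum_mat / cnt_mat # NaN where a subject has no data at an offset
  complete <- rowSums(!is.finite(subj_mat)) == 0
  if (any(!complete)) {
    warning(sum(!complete),
            " subject(s) dropped from alignment (no valid data at some offset)")
    subj_mat <- subj_mat[complete, , drop = FALSE]
  }
  if (nrow(subj_mat) == 0) {
    stop("data error: no subject has change-point-aligned data", call. = FALSE)
  }
  base_cols <- which(offs %in% c(-2L, -1L))
  subj_base <- rowMeans(subj_mat[, base_cols, drop = FALSE])
  structure(
    list(offsets = offs,
         mean_curve = colMeans(subj_mat),
         sem_curve = apply(subj_mat, 2, stats::sd) / sqrt(nrow(subj_mat)),
         baseline = mean(subj_base),
         subject_matrix = subj_mat,
         subject_baselines = subj_base,
         n_subjects = nrow(subj_mat)),
    class = "lr_dynamics"
  )
}

#' @export
print.lr_dynamics <- function(x, ...) {
  cat(sprintf("<lr_dynamics> %d subjects, offsets %d..%d (no 0)\n",
              x$n_subjects, min(x$offsets), max(x$offsets)))
  cat(sprintf("  baseline %.3f; curve: %s\n", x$baseline,
              paste(sprintf("%+d:%.2f", x$offsets, x$mean_curve), collapse = " ")))
  invisible(x)
}

#' @export
plot.lr_dynamics <- function(x, ...) {
  graphics::plot(x$offsets, x$mean_curve, type = "b", pch = 16,
                 xlab = "observation relative to change point",
                 ylab = "learning rate", ...)
  graphics::arrows(x$offsets, x$mean_curve - x$sem_curve,
                   x$offsets, x$mean_curve + x$sem_curve,
                   angle = 90, code = 3, length = 0.03)
  graphics::abline(h = x$baseline, lty = 2)
  invisible(x)
}

# Per-offset one-sample t statistics and two-tailed p-values; degenerate
# columns (zero variance) get t = 0 / p = 1 when the mean is also zero.
# Means and SDs at machine-rounding scale (< 1e-12 in learning-rate units)
# are treated as exact zeros so that cohorts with identically flat dynamics
# are never declared significant on floating-point residue.
offset_t_stats <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  s <- apply(D, 2, stats::sd)
  m[abs(m) < 1e-12] <- 0
  s[s < 1e-12] <- 0
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df = n - 1),
              ifelse(t_stat == 0, 1, 0))
  p[s == 0 & m == 0] <- 1
  list(t = t_stat, p = p)
}

# Maximal summed-|t| cluster statistic for one difference matrix.
cluster_stats <- function(D, alpha_level) {
  st <- offset_t_stats(D)
  below <- st$p < alpha_level
  clusters <- list()
  j <- 1L
  while (j <= length(below)) {
    if (below[j]) {
      k <- j
      while (k < length(below) && below[k + 1L]) k <- k + 1L
      clusters[[length(clusters) + 1L]] <-
        list(from = j, to = k, stat = sum(abs(st$t[j:k])))
      j <- k + 1L
    } else {
      j <- j + 1L
    }
  }
  list(t = st$t, p = st$p, clusters = clusters,
       max_stat = if (length(clusters)) max(vapply(clusters, `[[`, 0, "stat")) else 0)
}

#' Cluster-based permutation test of post-change learning-rate elevation
#'
#' Tests, per offset, whether the change-point-aligned learning rate differs
#' from the pre-change baseline, with family-wise error control over offsets
#' by cluster-based permutation. Per-subject difference curves (offset value
#' minus the subject's baseline) are t-tested per offset (two-tailed);
#' contiguous offsets with p below `alpha_level` form clusters scored by the
#' summed |t|; the null distribution of the maximal cluster score is built by
#' randomly sign-flipping subjects' difference curves. For small cohorts
#' (2^n no larger than `n_permutations`) all sign flips are enumerated and
#' the p-values are exact.
#'
#' @param dynamics An `lr_dynamics` object.
#' @param alpha_level Cluster-forming and cluster-significance level
#'   (default 0.05).
#' @param n_permutations Monte-Carlo permutations (default 10000; must be at
#'   least 100).
#' @param seed Seed for the Monte-Carlo sign flips.
#' @param test_offsets Offsets to test (default: all positive offsets).
#' @return A `cluster_test`: per-offset `t` and `p`, and a `clusters` data
#'   frame (from, to, stat, p, significant).
#' @export
cluster_permutation_test <- function(dynamics, alpha_level = 0.05,
                                     n_permutations = 10000L, seed = NULL,
                                     test_offsets = NULL) {
  stopifnot(inherits(dynamics, "lr_dynamics"))
  if (n_permutations < 100) {
    stop_config("n_permutations", "must be at least 100")
  }
  if (dynamics$n_subjects < 2) {
    stop("data error: need at least 2 subjects", call. = FALSE)
  }
  if (is.null(test_offsets)) test_offsets <- dynamics$offsets[dynamics$offsets > 0]
  cols <- match(test_offsets, dynamics$offsets)
  stopifnot(!anyNA(cols))
  D <- dynamics$subject_matrix[, cols, drop = FALSE] - dynamics$subject_baselines
  n <- nrow(D)
  obs <- cluster_stats(D, alpha_level)
  exact <- 2^n <= n_permutations
  if (length(obs$clusters)) {
    if (exact) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      null_max <- apply(signs, 1, function(e) cluster_stats(e * D, alpha_level)$max_stat)
      p_cl <- vapply(obs$clusters, function(cl) mean(null_max >= cl$stat), 0)
    } else {
      null_max <- with_seed(seed, {
        vapply(seq_len(n_permutations), function(i) {
          e <- sample(c(-1, 1), n, replace = TRUE)
          cluster_stats(e * D, alpha_level)$max_stat
        }, 0)
      })
      # observed labelling counts as one permutation
      p_cl <- vapply(obs$clusters,
                     function(cl) (1 + sum(null_max >= cl$stat)) / (n_permutations + 1),
                     0)
    }
  } else {
    p_cl <- numeric(0)
  }
  cl_df <- data.frame(
    from_offset = vapply(obs$clusters, function(cl) test_offsets[cl$from], 0L),
    to_offset = vapply(obs$clusters, function(cl) test_offsets[cl$to], 0L),
    stat = vapply(obs$clusters, `[[`, 0, "stat"),
    p = p_cl
  )
  cl_df$significant <- cl_df$p < alpha_level
  structure(
    list(offsets = test_offsets, t = obs$t, p_uncorrected = obs$p,
         clusters = cl_df, alpha_level = alpha_level, exact = exact,
         n_subjects = n),
    class = "cluster_test"
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d subjects, %s p-values\n", x$n_subjects,
              if (x$exact) "exact (full enumeration)" else "permutation"))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}

#' Estimate accuracy against the normative observer
#'
#' Per subject, the Pearson correlation between the subject's and the
#' normative estimates over all pooled observations, plus a calibration
#' curve: subject estimates averaged within equal quantile bins of the
#' normative estimate (within subject, then across subjects).
#'
#' @param traces List of `estimate_trace` objects.
#' @param normative_traces List of `normative_trace` objects covering the
#'   sequences appearing in `traces` (matched by `sequence_id`).
#' @param n_bins Number of quantile bins (default 6).
#' @return An `accuracy_result`: `per_subject` (subject_id, r, n, degenerate
#'   flag), `r_mean`, `r_sem`, `calibration` data frame.
#' @export
estimate_accuracy <- function(traces, normative_traces, n_bins = 6L) {
  check_number(n_bins, "n_bins", 2)
  norm_map <- stats::setNames(
    normative_traces,
    vapply(normative_traces, `[[`, "", "sequence_id")
  )
  subj <- vapply(traces, function(tr) tr$agent_id, "")
  per_subject <- list()
  calib <- list()
  for (sid in unique(subj)) {
    vs <- vn <- list()
    for (tr in traces[subj == sid]) {
      nt <- norm_map[[tr$sequence_id]]
      if (is.null(nt)) stop("data error: no normative trace for sequence ",
                            tr$sequence_id, call. = FALSE)
      vs[[length(vs) + 1L]] <- tr$v[-1]
      vn[[length(vn) + 1L]] <- nt$v
    }
    vs <- unlist(vs)
    vn <- unlist(vn)
    degenerate <- stats::sd(vs) == 0 || stats::sd(vn) == 0
    r <- if (degenerate) NA_real_ else stats::cor(vs, vn)
    per_subject[[sid]] <- data.frame(subject_id = sid, r = r, n = length(vs),
                                     degenerate = degenerate)
    qs <- stats::quantile(vn, probs = seq(0, 1, length.out = n_bins + 1L))
    bin <- cut(vn, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
    calib[[sid]] <- data.frame(
      subject_id = sid, bin = sort(unique(bin)),
      norm_mean = tapply(vn, bin, mean),
      subj_mean = tapply(vs, bin, mean)
    )
  }
  per_subject <- do.call(rbind, per_subject)
  calib <- do.call(rbind, calib)
  agg <- function(v) tapply(v, calib$bin, mean)
  sem <- tapply(calib$subj_mean, calib$bin,
                function(z) stats::sd(z) / sqrt(length(z)))
  rr <- per_subject$r[!per_subject$degenerate]
  structure(
    list(per_subject = per_subject,
         r_mean = mean(rr),
         r_sem = stats::sd(rr) / sqrt(length(rr)),
         calibration = data.frame(bin = sort(unique(calib$bin)),
                                  norm_mean = agg(calib$norm_mean),
                                  subj_mean = agg(calib$subj_mean),
                                  subj_sem = sem)),
    class = "accuracy_result"
  )
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %d subjects, Pearson r = %.3f +/- %.3f (mean +/- SEM)\n",
              nrow(x$per_subject), x$r_mean, x$r_sem))
  invisible(x)
}

#' Update-frequency statistics of report traces
#'
#' An update is any report change larger than `threshold` (in normalized
#' slider units). Returns the fraction of updates occurring after exactly one
#' observation (gap 1 since the previous update, counting the session start
#' as position 0) and the mean number of observations per update, pooled
#' over traces and per trace.
#'
#' @param traces List of `estimate_trace` objects.
#' @param threshold Minimum |report change| counting as an update
#'   (default 1e-6).
#' @return List with `n_updates`, `frac_single`, `mean_gap` (NA and
#'   `degenerate = TRUE` if no trace ever updates) and a `per_trace` data
#'   frame.
#' @export
update_frequency_stats <- function(traces, threshold = 1e-6) {
  gaps_all <- list()
  per_trace <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    up_t <- which(abs(diff(tr$v)) > threshold)
    gaps <- diff(c(0L, up_t))
    gaps_all[[i]] <- gaps
    per_trace[[i]] <- data.frame(
      subject_id = tr$agent_id, sequence_id = tr$sequence_id,
      n_updates = length(up_t),
      frac_single = if (length(gaps)) mean(gaps == 1) else NA_real_,
      mean_gap = if (length(gaps)) mean(gaps) else NA_real_
    )
  }
  gaps <- unlist(gaps_all)
  list(
    n_updates = length(gaps),
    frac_single = if (length(gaps)) mean(gaps == 1) else NA_real_,
    mean_gap = if (length(gaps)) mean(gaps) else NA_real_,
    degenerate = length(gaps) == 0,
    per_trace = do.call(rbind, per_trace)
  )
}
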