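#' Bias/variance decomposition of group estimation error
#'
#' When several subjects see the same sequence, the mean squared error
#' between the normative estimate and the subjects' estimates at a given
#' observation splits exactly into a squared bias error (how far the cohort
#' mean sits from the normative estimate) and a variance error (how much
#' subjects spread around their own mean):
#' \deqn{mse = \frac{1}{N}\sum_i (v^n - v^{s(i)})^2
#'   = (v^n - \bar v^s)^2 + \frac{1}{N}\sum_i (\bar v^s - v^{s(i)})^2.}
#' Cells (sequence, observation) with fewer than `min_subjects` estimates
#' are skipped and counted. Totals sum the per-cell values across all cells,
#' unweighted by default; `weight_by_n` weights each cell by its number of
#' subjects. Proportions are the bias and variance shares of the total mse,
#' in percent.
#'
#' @param traces List of `estimate_trace` objects (several subjects per
#'   sequence).
#' @param normative_traces Normative traces matched by `sequence_id`.
#' @param min_subjects Minimum estimates per cell (default 2).
#' @param weight_by_n Weight cells by subject count when summing totals
#'   (default FALSE).
#' @return An `mse_decomposition`: `per_cell` data frame (sequence_id, t, n,
#'   mse, sbe, var), `per_sequence` totals, `totals`, `proportions`
#'   (`sbe_pct`, `var_pct`), `n_skipped`.
#' @export
decompose_mse <- function(traces, normative_traces, min_subjects = 2L,
                          weight_by_n = FALSE) {
  check_number(min_subjects, "min_subjects", 2)
  norm_map <- stats::setNames(
    normative_traces,
    vapply(normative_traces, `[[`, "", "sequence_id")
  )
  seq_ids <- vapply(traces, `[[`, "", "sequence_id")
  cells <- list()
  n_skipped <- 0L
  for (sid in unique(seq_ids)) {
    nt <- norm_map[[sid]]
    if (is.null(nt)) stop("data error: no normative trace for sequence ",
                          sid, call. = FALSE)
    V <- vapply(traces[seq_ids == sid], function(tr) tr$v[-1],
                numeric(nt$n_obs)) # observations x subjects
    V <- matrix(V, nrow = nt$n_obs)
    n_sub <- ncol(V)
    if (n_sub < min_subjects) {
      n_skipped <- n_skipped + nt$n_obs
      next
    }
    vbar <- rowMeans(V)
    mse <- rowMeans((V - nt$v)^2)
    sbe <- (nt$v - vbar)^2
    vr <- rowMeans((V - vbar)^2)
    cells[[sid]] <- data.frame(sequence_id = sid, t = seq_len(nt$n_obs),
                               n = n_sub, mse = mse, sbe = sbe, var = vr)
  }
  if (!length(cells)) {
    stop("data error: no cell has enough subject estimates", call. = FALSE)
  }
  if (n_skipped > 0) {
    message(n_skipped, " cell(s) skipped (fewer than ", min_subjects,
            " estimates)")
  }
  per_cell <- do.call(rbind, cells)
  rownames(per_cell) <- NULL
  w <- if (weight_by_n) per_cell$n else rep(1, nrow(per_cell))
  per_sequence <- do.call(rbind, lapply(split(
    data.frame(mse = per_cell$mse * w, sbe = per_cell$sbe * w,
               var = per_cell$var * w, sequence_id = per_cell$sequence_id),
    per_cell$sequence_id
  ), function(d) data.frame(sequence_id = d$sequence_id[1],
                            mse = sum(d$mse), sbe = sum(d$sbe),
                            var = sum(d$var))))
  rownames(per_sequence) <- NULL
  totals <- c(mse = sum(per_sequence$mse), sbe = sum(per_sequence$sbe),
              var = sum(per_sequence$var))
  structure(
    list(per_cell = per_cell, per_sequence = per_sequence, totals = totals,
         proportions = c(sbe_pct = 100 * totals[["sbe"]] / totals[["mse"]],
                         var_pct = 100 * totals[["var"]] / totals[["mse"]]),
         n_skipped = n_skipped, weight_by_n = weight_by_n),
    class = "mse_decomposition"
  )
}

#' @export
print.mse_decomposition <- function(x, ...) {
  cat(sprintf("<mse_decomposition> %d cells over %d sequence(s)\n",
              nrow(x$per_cell), nrow(x$per_sequence)))
  cat(sprintf("  bias %.1f%% / variance %.1f%% of total mse %.4g\n",
              x$proportions[["sbe_pct"]], x$proportions[["var_pct"]],
              x$totals[["mse"]]))
  if (!is.null(x$se)) {
    cat(sprintf("  bootstrap SE: bias %.2f, variance %.2f (%d resamples)\n",
                x$se[["sbe_pct"]], x$se[["var_pct"]], x$n_boot))
  }
  invisible(x)
}

#' Bootstrap standard errors of the bias/variance proportions
#'
#' Resamples sequences (not subjects) with replacement, recomputes the bias
#' and variance proportions on each resampled set, and returns the standard
#' deviation across resamples as the standard error (the margin of error of
#' a 68% confidence interval).
#'
#' @param decomp An `mse_decomposition`.
#' @param n_boot Number of bootstrap resamples (default 10000, minimum 100).
#' @param seed Integer seed; SEs are deterministic under it.
#' @return The `mse_decomposition` with fields `se` (named vector `sbe_pct`,
#'   `var_pct`) and `n_boot` added.
#' @export
bootstrap_se <- function(decomp, n_boot = 10000L, seed = NULL) {
  stopifnot(inherits(decomp, "mse_decomposition"))
  if (n_boot < 100) stop_config("n_boot", "must be at least 100")
  ps <- decomp$per_sequence
  K <- nrow(ps)
  props <- with_seed(seed, {
    idx <- matrix(sample.int(K, K * n_boot, replace = TRUE), nrow = K)
    vapply(seq_len(n_boot), function(b) {
      i <- idx[, b]
      tot_mse <- sum(ps$mse[i])
      c(100 * sum(ps$sbe[i]) / tot_mse, 100 * sum(ps$var[i]) / tot_mse)
    }, numeric(2))
  })
  decomp$se <- c(sbe_pct = stats::sd(props[1, ]), var_pct = stats::sd(props[2, ]))
  decomp$n_boot <- as.integer(n_boot)
  decomp
}
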