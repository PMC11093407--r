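#' Configuration for magnitude-task sequence generation
#'
#' The magnitude task presents observations drawn from a Gaussian around a
#' hidden mean that jumps at unpredictable change points. All values are in
#' normalized slider units on \[0, 1\].
#'
#' @param noise_sd Standard deviation of observations around the hidden mean
#'   (default 10/300, i.e. 10 screen pixels of a 300-pixel slider).
#' @param hazard Per-observation change-point probability outside the
#'   refractory period (default 1/10).
#' @param refractory Number of observations after a change point (and after
#'   the sequence start) during which the hazard is zero (default 3).
#' @param n_obs Sequence length (default 75).
#' @param mean_support Interval from which hidden means are drawn uniformly
#'   (default c(0.1, 0.9), keeping observations almost surely on-screen).
#'
#' @return An object of class `magnitude_config`.
#' @export
magnitude_config <- function(noise_sd = 10 / 300, hazard = 1 / 10,
                             refractory = 3L, n_obs = 75L,
                             mean_support = c(0.1, 0.9)) {
  check_number(noise_sd, "noise_sd", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(hazard, "hazard", 0, 1)
  check_number(refractory, "refractory", 0)
  check_number(n_obs, "n_obs", 1)
  check_interval(mean_support, "mean_support", 0, 1)
  structure(
    list(task = "magnitude", noise_sd = noise_sd, hazard = hazard,
         refractory = as.integer(refractory), n_obs = as.integer(n_obs),
         mean_support = mean_support),
    class = c("magnitude_config", "gen_config")
  )
}

#' Configuration for probability-task sequence generation
#'
#' The probability task presents binary observations (0 = yellow, 1 = blue)
#' drawn from a Bernoulli whose parameter jumps at change points. At each
#' change point the parameter is resampled uniformly on `p_support` subject to
#' a minimum multiplicative change of the odds p/(1-p), so that changes are
#' never imperceptibly small.
#'
#' @param hazard Per-observation change-point probability outside the
#'   refractory period (default 1/20).
#' @param refractory Zero-hazard observations after a change point (default 6).
#' @param n_obs Sequence length (default 75).
#' @param p_support Interval for the hidden probability (default c(0.1, 0.9)).
#' @param min_odds_factor Minimum factor by which the odds must change at a
#'   change point, in either direction (default 4).
#'
#' @return An object of class `probability_config`.
#' @export
probability_config <- function(hazard = 1 / 20, refractory = 6L, n_obs = 75L,
                               p_support = c(0.1, 0.9), min_odds_factor = 4) {
  check_number(hazard, "hazard", 0, 1)
  check_number(refractory, "refractory", 0)
  check_number(n_obs, "n_obs", 1)
  check_interval(p_support, "p_support", 0, 1, strict = TRUE)
  check_number(min_odds_factor, "min_odds_factor", 1)
  structure(
    list(task = "probability", hazard = hazard,
         refractory = as.integer(refractory), n_obs = as.integer(n_obs),
         p_support = p_support, min_odds_factor = min_odds_factor),
    class = c("probability_config", "gen_config")
  )
}

new_obs_sequence <- function(task, x, h, cp, config, seed,
                             sequence_id = NA_character_) {
  structure(
    list(task = task, x = x, h = h, cp = cp, n_obs = length(x),
         config = config, seed = seed, sequence_id = sequence_id),
    class = "obs_sequence"
  )
}

# Draw change-point times for one sequence. The sequence start is treated as
# a change point for refractory accounting: no change can occur during the
# first `refractory` observations.
draw_changepoints <- function(n_obs, hazard, refractory) {
  cp <- logical(n_obs)
  last_change <- 1L
  t <- 2L
  while (t <= n_obs) {
    eligible <- (t - last_change) > refractory
    if (eligible && stats::runif(1) < hazard) {
      cp[t] <- TRUE
      last_change <- t
    }
    t <- t + 1L
  }
  cp
}

#' Generate one magnitude-task observation sequence
#'
#' The hidden mean is drawn uniformly from `mean_support` at the start and
#' redrawn at each change point; observations are Gaussian around it, clipped
#' to the slider range \[0, 1\].
#'
#' @param config A [magnitude_config()].
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return An `obs_sequence` with fields `x` (observations), `h` (hidden
#'   mean per observation) and `cp` (TRUE at the first observation of a new
#'   regime; `cp[1]` is FALSE).
#' @export
generate_magnitude_sequence <- function(config = magnitude_config(), seed = NULL) {
  stopifnot(inherits(config, "magnitude_config"))
  with_seed(seed, {
    cp <- draw_changepoints(config$n_obs, config$hazard, config$refractory)
    h <- numeric(config$n_obs)
    cur <- stats::runif(1, config$mean_support[1], config$mean_support[2])
    for (t in seq_len(config$n_obs)) {
      if (cp[t]) cur <- stats::runif(1, config$mean_support[1], config$mean_support[2])
      h[t] <- cur
    }
    x <- clip01(stats::rnorm(config$n_obs, mean = h, sd = config$noise_sd))
    new_obs_sequence("magnitude", x, h, cp, config, seed)
  })
}

# Resample a Bernoulli parameter uniformly on `support` subject to the
# minimum odds-change constraint relative to `p_old`.
resample_p <- function(p_old, support, min_odds_factor, max_iter = 10000L) {
  # fail fast if no admissible value exists in the support
  o <- odds(p_old)
  lo_ok <- odds(support[1]) <= o / min_odds_factor
  hi_ok <- odds(support[2]) >= o * min_odds_factor
  if (!lo_ok && !hi_ok) {
    stop_config("min_odds_factor",
                "makes the admissible support empty for the current value")
  }
  for (i in seq_len(max_iter)) {
    p_new <- stats::runif(1, support[1], support[2])
    r <- odds(p_new) / o
    if (r >= min_odds_factor || r <= 1 / min_odds_factor) return(p_new)
  }
  stop("rejection sampling failed to satisfy the odds constraint after ",
       max_iter, " iterations", call. = FALSE)
}

#' Generate one probability-task observation sequence
#'
#' The hidden probability is uniform on `p_support` initially and resampled
#' at each change point under the minimum odds-change constraint (rejection
#' sampling); observations are Bernoulli draws.
#'
#' @param config A [probability_config()].
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return An `obs_sequence` with binary `x`.
#' @export
generate_probability_sequence <- function(config = probability_config(), seed = NULL) {
  stopifnot(inherits(config, "probability_config"))
  with_seed(seed, {
    cp <- draw_changepoints(config$n_obs, config$hazard, config$refractory)
    h <- numeric(config$n_obs)
    cur <- stats::runif(1, config$p_support[1], config$p_support[2])
    for (t in seq_len(config$n_obs)) {
      if (cp[t]) cur <- resample_p(cur, config$p_support, config$min_odds_factor)
      h[t] <- cur
    }
    x <- as.numeric(stats::runif(config$n_obs) < h)
    new_obs_sequence("probability", x, h, cp, config, seed)
  })
}

#' Generate a set of independent sequences
#'
#' Per-sequence seeds are derived deterministically from the master seed, so
#' the set is reproducible as a whole and each member individually.
#'
#' @param config A [magnitude_config()] or [probability_config()].
#' @param n_sequences Number of sequences (the reference designs use 100 for
#'   the magnitude task and 150 for the probability task).
#' @param seed Master integer seed.
#' @return A list of `obs_sequence` objects with `sequence_id` set to
#'   `"seq001"`, `"seq002"`, ...
#' @export
generate_sequence_set <- function(config, n_sequences, seed = NULL) {
  check_number(n_sequences, "n_sequences", 1)
  gen <- switch(config$task,
    magnitude = generate_magnitude_sequence,
    probability = generate_probability_sequence,
    stop_config("config", "must be a magnitude or probability config")
  )
  seeds <- derive_seeds(seed, n_sequences)
  out <- vector("list", n_sequences)
  for (i in seq_len(n_sequences)) {
    s <- gen(config, seeds[i])
    s$sequence_id <- sprintf("seq%03d", i)
    out[[i]] <- s
  }
  out
}

#' @export
print.obs_sequence <- function(x, ...) {
  cat(sprintf("<obs_sequence> %s task, %d observations, %d change point(s)\n",
              x$task, x$n_obs, sum(x$cp)))
  cat(sprintf("  hidden value range: [%.3f, %.3f]\n", min(x$h), max(x$h)))
  invisible(x)
}

#' @export
plot.obs_sequence <- function(x, ...) {
  graphics::plot(seq_len(x$n_obs), x$x, pch = 16, col = "grey40",
                 xlab = "observation", ylab = "normalized value",
                 ylim = c(0, 1), ...)
  graphics::lines(seq_len(x$n_obs), x$h, lty = 2)
  graphics::abline(v = which(x$cp) - 0.5, col = "grey70", lty = 3)
  invisible(x)
}

#' @export
as.data.frame.obs_sequence <- function(x, ...) {
  data.frame(task = x$task, sequence_id = x$sequence_id,
             t = seq_len(x$n_obs), x = x$x, h = x$h, cp = x$cp,
             stringsAsFactors = FALSE)
}
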