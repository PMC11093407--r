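#' Configuration for the grid-based Bayesian filter (probability task)
#'
#' The filter tracks the full posterior over the hidden Bernoulli parameter
#' on a discrete grid, assuming a constant hazard with uniform resampling on
#' `p_support`. It deliberately ignores the generative refractory period and
#' odds constraint, so the assumed process is slightly simpler than the true
#' one.
#'
#' @param hazard Assumed per-observation change-point probability
#'   (default 1/20, matching the generative process).
#' @param p_support Support of the hidden probability (default c(0.1, 0.9)).
#' @param grid_size Number of grid points (default 301). Masses follow the
#'   midpoint rule: the support is split into `grid_size` equal cells and the
#'   posterior mass lives on the cell midpoints.
#'
#' @return An object of class `probability_filter_config`.
#' @export
probability_filter_config <- function(hazard = 1 / 20,
                                      p_support = c(0.1, 0.9),
                                      grid_size = 301L) {
  check_number(hazard, "hazard", 0, 1)
  check_interval(p_support, "p_support", 0, 1, strict = TRUE)
  check_number(grid_size, "grid_size", 3)
  structure(
    list(hazard = hazard, p_support = p_support,
         grid_size = as.integer(grid_size)),
    class = "probability_filter_config"
  )
}

#' Configuration for the reduced Bayesian model (magnitude task)
#'
#' The reduced model tracks only the first two moments of the change-point
#' posterior: the estimated latent mean `b` and the relative uncertainty
#' `tau` (uncertainty about the mean relative to the predictive variance of
#' observations).
#'
#' @param obs_sd Observation standard deviation N assumed by the observer
#'   (default 10/300).
#' @param hazard Assumed change-point probability H (default 1/10).
#' @param x_support Observation range over which the change likelihood is
#'   uniform (default c(0, 1), density 1 in normalized units).
#' @param b0,tau0 Initial estimate and initial relative uncertainty
#'   (defaults 0.5 and 0.5: slider starts mid-scale, moderate uncertainty).
#' @param tau_clamp `tau` is clamped to \[tau_clamp, 1 - tau_clamp\] to keep
#'   the predictive variance finite (default 1e-6).
#'
#' @return An object of class `magnitude_model_config`.
#' @export
magnitude_model_config <- function(obs_sd = 10 / 300, hazard = 1 / 10,
                                   x_support = c(0, 1), b0 = 0.5, tau0 = 0.5,
                                   tau_clamp = 1e-6) {
  check_number(obs_sd, "obs_sd", 0, Inf, strict_lower = TRUE)
  check_number(hazard, "hazard", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_interval(x_support, "x_support", -Inf, Inf)
  check_number(b0, "b0", 0, 1)
  check_number(tau0, "tau0", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_number(tau_clamp, "tau_clamp", 0, 0.5, strict_lower = TRUE)
  structure(
    list(obs_sd = obs_sd, hazard = hazard, x_support = x_support,
         b0 = b0, tau0 = tau0, tau_clamp = tau_clamp),
    class = "magnitude_model_config"
  )
}

new_normative_trace <- function(task, v, u, u_prev, omega, alpha,
                                sequence_id = NA_character_, extra = list()) {
  structure(
    c(list(task = task, v = v, u = u, u_prev = u_prev, omega = omega,
           alpha = alpha, n_obs = length(v), sequence_id = sequence_id,
           v0 = 0.5), extra),
    class = "normative_trace"
  )
}

# Midpoints of grid_size equal cells covering the support.
filter_grid <- function(config) {
  lo <- config$p_support[1]
  hi <- config$p_support[2]
  n <- config$grid_size
  lo + (seq_len(n) - 0.5) * (hi - lo) / n
}

#' Run the Bayesian filter on a probability-task sequence
#'
#' Sequentially applies the predict step (mix the previous posterior with the
#' uniform change distribution, weighted by the hazard) and the update step
#' (multiply by the Bernoulli likelihood, renormalize). Per observation it
#' returns the posterior-mean estimate `v`, the prior uncertainty `u` (SD of
#' the change-point-predicted prior, the distribution actually multiplied
#' with the likelihood), the SD of the previous posterior `u_prev`, the
#' change-point probability `omega`
#' \deqn{\Omega_t = p(x_t | h_t \ne h_{t-1})\, H \;/\; p(x_t | x_{1:t-1}),}
#' and the apparent learning rate `alpha` of the filter's own estimates
#' (initial report 0.5).
#'
#' At t = 1 there is no previous posterior; `omega[1]` equals the hazard by
#' construction and analyses typically exclude t = 1.
#'
#' @param seq An `obs_sequence` with `task == "probability"` (binary `x`).
#' @param config A [probability_filter_config()].
#' @return A `normative_trace`.
#' @export
run_probability_filter <- function(seq, config = probability_filter_config()) {
  stopifnot(inherits(seq, "obs_sequence"))
  if (seq$task != "probability") {
    stop("data error: run_probability_filter expects a probability-task sequence",
         call. = FALSE)
  }
  x <- seq$x
  if (!all(x %in% c(0, 1))) {
    stop("data error: probability-task observations must be 0 or 1", call. = FALSE)
  }
  g <- filter_grid(config)
  n <- length(g)
  H <- config$hazard
  unif <- rep(1 / n, n)
  post <- unif # initial prior: uniform on the support
  T_ <- seq$n_obs
  v <- u <- u_prev <- omega <- numeric(T_)
  for (t in seq_len(T_)) {
    u_prev[t] <- sqrt(max(0, sum(g^2 * post) - sum(g * post)^2))
    pred <- (1 - H) * post + H * unif
    u[t] <- sqrt(max(0, sum(g^2 * pred) - sum(g * pred)^2))
    lik <- if (x[t] == 1) g else 1 - g
    evidence <- sum(lik * pred)
    omega[t] <- sum(lik * unif) * H / evidence
    post <- lik * pred / evidence
    post <- post / sum(post)
    v[t] <- sum(g * post)
  }
  v_prev <- c(0.5, v[-T_])
  alpha <- (v - v_prev) / (x - v_prev)
  new_normative_trace("probability", v, u, u_prev, omega, alpha,
                      sequence_id = seq$sequence_id,
                      extra = list(config = config, grid = g,
                                   posterior = post))
}

#' Run the reduced Bayesian model on a magnitude-task sequence
#'
#' Iterates the two-moment approximation of the Gaussian change-point
#' posterior. Writing N for the observation SD, H for the hazard, `b_t` for
#' the current mean estimate and `tau_t` for the relative uncertainty, each
#' observation is processed as:
#' \deqn{\Omega_t = \mathcal{U}(x_t) H / (\mathcal{U}(x_t) H +
#'   \mathcal{N}(x_t; b_t, \sigma_t^2)(1 - H))}
#' \deqn{\sigma_t^2 = N^2 + \tau_t N^2 / (1 - \tau_t)}
#' \deqn{\eta_t = \tau_t + (1 - \tau_t)\Omega_t}
#' \deqn{b_{t+1} = b_t + \eta_t (x_t - b_t), \quad v_t = b_{t+1}}
#' with the relative-uncertainty update
#' \deqn{\tau_{t+1} = Q / (Q + N^2), \quad
#'   Q = N^2\Omega_t + (1-\Omega_t)\tau_t N^2 +
#'       \Omega_t(1-\Omega_t)(x_t\tau_t + b_t(1-\tau_t) - x_t)^2}
#' and prior uncertainty \eqn{u_t = \sqrt{\tau_t}\,\sigma_t}.
#'
#' The returned `alpha` applies the apparent-learning-rate definition to the
#' model's own estimate trace; wherever the prediction error is nonzero it
#' equals the internal `eta` exactly, since
#' \eqn{v_t - v_{t-1} = \eta_t (x_t - v_{t-1})}.
#'
#' @param seq An `obs_sequence` with `task == "magnitude"` (`x` in \[0, 1\]).
#' @param config A [magnitude_model_config()].
#' @return A `normative_trace` with extra per-observation fields `eta`,
#'   `tau` and `sigma2`.
#' @export
run_magnitude_model <- function(seq, config = magnitude_model_config()) {
  stopifnot(inherits(seq, "obs_sequence"))
  if (seq$task != "magnitude") {
    stop("data error: run_magnitude_model expects a magnitude-task sequence",
         call. = FALSE)
  }
  x <- seq$x
  if (any(x < 0 | x > 1)) {
    stop("data error: magnitude observations must lie in [0, 1]", call. = FALSE)
  }
  N2 <- config$obs_sd^2
  H <- config$hazard
  u_dens <- 1 / (config$x_support[2] - config$x_support[1])
  T_ <- seq$n_obs
  v <- u <- omega <- eta <- tau_out <- sigma2_out <- numeric(T_)
  b <- config$b0
  tau <- config$tau0
  for (t in seq_len(T_)) {
    tau <- min(max(tau, config$tau_clamp), 1 - config$tau_clamp)
    sigma2 <- N2 + tau * N2 / (1 - tau)
    om <- u_dens * H /
      (u_dens * H + stats::dnorm(x[t], b, sqrt(sigma2)) * (1 - H))
    et <- tau + (1 - tau) * om
    u[t] <- sqrt(tau * sigma2)
    omega[t] <- om
    eta[t] <- et
    tau_out[t] <- tau
    sigma2_out[t] <- sigma2
    q <- N2 * om + (1 - om) * tau * N2 +
      om * (1 - om) * (x[t] * tau + b * (1 - tau) - x[t])^2
    b_new <- b + et * (x[t] - b)
    v[t] <- b_new
    tau <- q / (q + N2)
    b <- b_new
  }
  v_prev <- c(config$b0, v[-T_])
  alpha <- (v - v_prev) / (x - v_prev)
  new_normative_trace("magnitude", v, u, u_prev = u, omega, alpha,
                      sequence_id = seq$sequence_id,
                      extra = list(config = config, eta = eta, tau = tau_out,
                                   sigma2 = sigma2_out))
}

#' Run the task-appropriate normative observer on a sequence
#'
#' Dispatches to [run_magnitude_model()] or [run_probability_filter()]
#' according to the sequence's task, with observer parameters defaulting to
#' the sequence's own generative parameters (the observer knows the true
#' process).
#'
#' @param seq An `obs_sequence`.
#' @param config Optional observer configuration; if NULL, built from the
#'   sequence's generative config.
#' @return A `normative_trace`.
#' @export
normative_fit <- function(seq, config = NULL) {
  stopifnot(inherits(seq, "obs_sequence"))
  if (seq$task == "magnitude") {
    if (is.null(config)) {
      config <- magnitude_model_config(obs_sd = seq$config$noise_sd,
                                       hazard = seq$config$hazard)
    }
    run_magnitude_model(seq, config)
  } else {
    if (is.null(config)) {
      config <- probability_filter_config(hazard = seq$config$hazard,
                                          p_support = seq$config$p_support)
    }
    run_probability_filter(seq, config)
  }
}

#' Spearman correlation between change-point probability and |prediction error|
#'
#' Pools `(omega, |x_t - v_{t-1}|)` pairs over all observations of all
#' sequences (excluding t = 1, where the change-point probability is a
#' flagged initialization value) and returns the Spearman rank correlation.
#' For the normative observers on task-typical sequences this correlation is
#' very high: the change-point probability is essentially a monotone
#' transform of the size of the surprise.
#'
#' @param traces List of `normative_trace` objects.
#' @param seqs List of matching `obs_sequence` objects.
#' @param exclude_first Drop t = 1 of every sequence (default TRUE).
#' @return The Spearman rank correlation (single number).
#' @export
measure_determinant_correlation <- function(traces, seqs, exclude_first = TRUE) {
  if (length(traces) == 0 || length(traces) != length(seqs)) {
    stop("data error: need non-empty, aligned lists of traces and sequences",
         call. = FALSE)
  }
  om <- pe <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    sq <- seqs[[i]]
    stopifnot(tr$n_obs == sq$n_obs)
    v_prev <- c(tr$v0, tr$v[-tr$n_obs])
    keep <- if (exclude_first) -1L else seq_len(tr$n_obs)
    om[[i]] <- tr$omega[keep]
    pe[[i]] <- abs(sq$x - v_prev)[keep]
  }
  stats::cor(unlist(om), unlist(pe), method = "spearman")
}

#' @export
print.normative_trace <- function(x, ...) {
  cat(sprintf("<normative_trace> %s task, %d observations\n", x$task, x$n_obs))
  cat(sprintf("  final estimate %.3f; omega range [%.2g, %.2g]; u range [%.2g, %.2g]\n",
              x$v[x$n_obs], min(x$omega), max(x$omega), min(x$u), max(x$u)))
  invisible(x)
}

#' @export
plot.normative_trace <- function(x, seq = NULL, ...) {
  t <- seq_len(x$n_obs)
  graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  graphics::plot(t, x$v, type = "l", ylim = c(0, 1), ylab = "estimate v", ...)
  if (!is.null(seq)) {
    graphics::points(t, seq$x, pch = 16, col = "grey60", cex = 0.5)
    graphics::lines(t, seq$h, lty = 2)
  }
  graphics::plot(t, x$omega, type = "h", ylab = expression(Omega))
  graphics::plot(t, x$u, type = "l", ylab = "prior uncertainty u")
  invisible(x)
}
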