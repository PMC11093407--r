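#' Configuration for a simulated learning agent
#'
#' Five agent kinds are available:
#' \describe{
#'   \item{`delta_rule`}{fixed learning rate: `v_t = v_{t-1} + alpha (x_t - v_{t-1})`.}
#'   \item{`normative`}{reports the normative observer's posterior-mean estimates.}
#'   \item{`report_noise`}{normative estimates plus i.i.d. Gaussian report
#'     noise, clipped to the slider range.}
#'   \item{`learning_noise_constant`}{delta-rule update corrupted by Gaussian
#'     noise of constant SD added to every update — a non-adaptive learner
#'     whose apparent learning rate fluctuates only through noise.}
#'   \item{`learning_noise_scaled`}{as above with the noise SD scaled by the
#'     absolute prediction error.}
#' }
#' The two learning-noise kinds serve as controls: their estimate variability
#' is autocorrelated like real reports, yet they make no true learning-rate
#' adjustment, so any apparent change-point dynamics they show would be a
#' measurement artifact.
#'
#' @param kind One of the five kinds above.
#' @param alpha Fixed learning rate in \[0, 1\] (delta_rule and the two
#'   learning-noise kinds).
#' @param noise_sd Noise SD in normalized slider units (default 0.05; for
#'   `learning_noise_scaled` it multiplies the absolute prediction error).
#'
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(kind = c("delta_rule", "normative", "report_noise",
                                  "learning_noise_constant",
                                  "learning_noise_scaled"),
                         alpha = NULL, noise_sd = 0.05) {
  kind <- match.arg(kind)
  needs_alpha <- kind %in% c("delta_rule", "learning_noise_constant",
                             "learning_noise_scaled")
  if (needs_alpha) {
    if (is.null(alpha)) stop_config("alpha", paste0("is required for kind ", kind))
    check_number(alpha, "alpha", 0, 1)
  }
  check_number(noise_sd, "noise_sd", 0)
  structure(list(kind = kind, alpha = alpha, noise_sd = noise_sd),
            class = "agent_config")
}

new_estimate_trace <- function(task, v, sequence_id, agent_id, kind) {
  structure(
    list(task = task, v = v, n_obs = length(v) - 1L,
         sequence_id = sequence_id, agent_id = agent_id, kind = kind),
    class = "estimate_trace"
  )
}

#' Simulate one agent's report trace on a sequence
#'
#' Reports start at the slider midpoint (`v[1]` is the pre-observation report
#' `v_0 = 0.5`) and all reports are clipped to \[0, 1\].
#'
#' @param seq An `obs_sequence`.
#' @param config An [agent_config()].
#' @param seed Integer seed for the agent's noise; simulation is
#'   deterministic under a fixed seed.
#' @param normative Optional precomputed `normative_trace` for `seq`
#'   (computed on demand for the kinds that need it).
#' @param agent_id Label stored on the trace.
#' @return An `estimate_trace` whose `v` has length `n_obs + 1`.
#' @export
simulate_agent <- function(seq, config, seed = NULL, normative = NULL,
                           agent_id = "agent1") {
  stopifnot(inherits(seq, "obs_sequence"), inherits(config, "agent_config"))
  x <- seq$x
  T_ <- seq$n_obs
  v <- numeric(T_ + 1L)
  v[1] <- 0.5
  kind <- config$kind
  if (kind %in% c("normative", "report_noise")) {
    if (is.null(normative)) normative <- normative_fit(seq)
    stopifnot(normative$n_obs == T_)
  }
  with_seed(seed, {
    if (kind == "normative") {
      v[-1] <- normative$v
    } else if (kind == "report_noise") {
      v[-1] <- clip01(normative$v + stats::rnorm(T_, 0, config$noise_sd))
    } else {
      a <- config$alpha
      for (t in seq_len(T_)) {
        upd <- a * (x[t] - v[t])
        if (kind == "learning_noise_constant") {
          upd <- upd + stats::rnorm(1, 0, config$noise_sd)
        } else if (kind == "learning_noise_scaled") {
          upd <- upd + stats::rnorm(1, 0, config$noise_sd * abs(x[t] - v[t]))
        }
        v[t + 1L] <- clip01(v[t] + upd)
      }
    }
  })
  new_estimate_trace(seq$task, v, seq$sequence_id, agent_id, kind)
}

#' Simulate a cohort of agents over a sequence set
#'
#' Each agent is assigned `n_sessions` sequences sampled without replacement
#' from the set, so different agents share sequences — the overlap is what
#' makes the group-level bias/variance decomposition possible. Normative
#' traces are computed once per sequence and shared across agents.
#'
#' @param seqs List of `obs_sequence` objects (a sequence set).
#' @param n_agents Number of agents (the reference cohort size is 96).
#' @param config An [agent_config()] used for every agent.
#' @param n_sessions Sequences per agent (reference designs: 10 magnitude,
#'   15 probability sessions per subject).
#' @param seed Master seed; assignment and noise are deterministic under it.
#' @return A list of `estimate_trace` objects with `agent_id` of the form
#'   `"agent001"`.
#' @export
simulate_cohort <- function(seqs, n_agents, config, n_sessions = 10L,
                            seed = NULL) {
  check_number(n_agents, "n_agents", 1)
  check_number(n_sessions, "n_sessions", 1)
  if (n_sessions > length(seqs)) {
    stop_config("n_sessions", "exceeds the number of available sequences")
  }
  norm_cache <- vector("list", length(seqs))
  needs_norm <- config$kind %in% c("normative", "report_noise")
  if (needs_norm) {
    for (i in seq_along(seqs)) norm_cache[[i]] <- normative_fit(seqs[[i]])
  }
  seeds <- derive_seeds(seed, n_agents * (1L + n_sessions))
  out <- list()
  k <- 0L
  for (a in seq_len(n_agents)) {
    assign_seed <- seeds[(a - 1L) * (1L + n_sessions) + 1L]
    idx <- with_seed(assign_seed, sample(length(seqs), n_sessions))
    for (j in seq_along(idx)) {
      i <- idx[j]
      k <- k + 1L
      out[[k]] <- simulate_agent(
        seqs[[i]], config,
        seed = seeds[(a - 1L) * (1L + n_sessions) + 1L + j],
        normative = norm_cache[[i]],
        agent_id = sprintf("agent%03d", a)
      )
    }
  }
  out
}

#' @export
print.estimate_trace <- function(x, ...) {
  cat(sprintf("<estimate_trace> %s task, agent %s on %s (%d observations, kind %s)\n",
              x$task, x$agent_id, x$sequence_id, x$n_obs, x$kind))
  invisible(x)
}
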