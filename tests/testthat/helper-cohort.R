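# Shared fixture builders. Everything is generated in code under fixed seeds.

make_seq_set <- function(task, n_seq, seed) {
  cfg <- if (task == "magnitude") magnitude_config() else probability_config()
  generate_sequence_set(cfg, n_seq, seed = seed)
}

seq_map <- function(seqs) {
  stats::setNames(seqs, vapply(seqs, `[[`, "", "sequence_id"))
}

# Cohort + learning-rate series + normative traces for a task in one call.
make_cohort_series <- function(task, kind, n_agents, n_seq, n_sessions,
                               seed, alpha = NULL, noise_sd = 0.05) {
  seqs <- make_seq_set(task, n_seq, seed)
  cohort <- simulate_cohort(seqs, n_agents,
                            agent_config(kind, alpha = alpha,
                                         noise_sd = noise_sd),
                            n_sessions, seed = seed + 1L)
  smap <- seq_map(seqs)
  series <- lapply(cohort, function(tr) {
    compute_learning_rates(tr, smap[[tr$sequence_id]])
  })
  list(seqs = seqs, cohort = cohort, series = series,
       normative = lapply(seqs, normative_fit))
}

# Build an estimate_trace directly from a report vector (v_0:T).
manual_trace <- function(v, task = "probability", sequence_id = "seq001",
                         agent_id = "agent001") {
  structure(list(task = task, v = v, n_obs = length(v) - 1L,
                 sequence_id = sequence_id, agent_id = agent_id,
                 kind = "manual"),
            class = "estimate_trace")
}

# Build a bare lr_series from an alpha vector and change-point flags.
manual_series <- function(alpha, cp, task = "probability",
                          subject_id = "s1", sequence_id = "seq001",
                          excluded = is.na(alpha)) {
  out <- data.frame(t = seq_along(alpha), alpha = alpha,
                    excluded = excluded, cp = cp)
  attr(out, "task") <- task
  attr(out, "subject_id") <- subject_id
  attr(out, "sequence_id") <- sequence_id
  class(out) <- c("lr_series", "data.frame")
  out
}

# Build an lr_dynamics object directly from a subject x offset matrix.
manual_dynamics <- function(subject_matrix, offsets = c(-2L, -1L, 1:8)) {
  base_cols <- which(offsets %in% c(-2L, -1L))
  subj_base <- rowMeans(subject_matrix[, base_cols, drop = FALSE])
  structure(
    list(offsets = offsets,
         mean_curve = colMeans(subject_matrix),
         sem_curve = apply(subject_matrix, 2, stats::sd) /
           sqrt(nrow(subject_matrix)),
         baseline = mean(subj_base),
         subject_matrix = subject_matrix,
         subject_baselines = subj_base,
         n_subjects = nrow(subject_matrix)),
    class = "lr_dynamics"
  )
}

# Independent oracle: posterior mean of a Bernoulli change-point process on
# a grid, by exhaustive enumeration of all change configurations. Shares
# only the grid discretization with the filter, not its recursion.
enum_posterior_mean <- function(x, hazard, grid) {
  T_ <- length(x)
  ng <- length(grid)
  # segment evidence m1[i,j] = E_g[prod lik_{i..j}], m2 same with extra g
  lik <- outer(grid, seq_len(T_), function(g, t) ifelse(x[t] == 1, g, 1 - g))
  m1 <- m2 <- matrix(NA_real_, T_, T_)
  for (i in seq_len(T_)) {
    prod_g <- rep(1, ng)
    for (j in i:T_) {
      prod_g <- prod_g * lik[, j]
      m1[i, j] <- mean(prod_g)
      m2[i, j] <- mean(grid * prod_g)
    }
  }
  configs <- as.matrix(expand.grid(rep(list(0:1), T_ - 1L)))
  num <- den <- 0
  for (r in seq_len(nrow(configs))) {
    c_vec <- configs[r, ]
    prior <- prod(ifelse(c_vec == 1, hazard, 1 - hazard))
    starts <- c(1L, which(c_vec == 1) + 1L)
    ends <- c(starts[-1] - 1L, T_)
    ev <- prod(m1[cbind(starts, ends)])
    last <- length(starts)
    e_last <- m2[starts[last], ends[last]] / m1[starts[last], ends[last]]
    num <- num + prior * ev * e_last
    den <- den + prior * ev
  }
  num / den
}
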