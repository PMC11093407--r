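test_that("apparent learning rates follow the update/error ratio", {
  s <- wrap <- adaptrate:::new_obs_sequence(
    "magnitude", x = c(1, 0.6, 0.55, 0.9), h = rep(0.5, 4),
    cp = rep(FALSE, 4), config = magnitude_config(), seed = NA, "seq001")
  # v_0 = 0.5; chosen so the four observations exercise the cases:
  # plain ratio, alpha = 1, alpha = 0, outlier
  v <- c(0.5, 0.8, 0.6, 0.6, 0.195)
  tr <- manual_trace(v, task = "magnitude")
  lr <- compute_learning_rates(tr, s)
  expect_equal(lr$alpha[1], 0.6)           # (0.8-0.5)/(1-0.5)
  expect_equal(lr$alpha[2], 1)             # v_t = x_t
  expect_equal(lr$alpha[3], 0)             # v_t = v_{t-1}
  expect_true(lr$excluded[4])              # (0.195-0.6)/(0.9-0.6) = -1.35
  lr_keep <- compute_learning_rates(tr, s, exclude_outliers = FALSE)
  expect_equal(lr_keep$alpha[4], -1.35)
})

test_that("zero prediction errors are excluded as undefined", {
  s <- adaptrate:::new_obs_sequence(
    "probability", x = c(1, 1), h = c(0.5, 0.5), cp = c(FALSE, FALSE),
    config = probability_config(), seed = NA, "seq001")
  tr <- manual_trace(c(0.5, 1, 1)) # after t=1 report sits exactly on x
  lr <- compute_learning_rates(tr, s)
  expect_false(lr$excluded[1])
  expect_true(lr$excluded[2])
  expect_error(compute_learning_rates(manual_trace(c(0.5, 1)), s), "data error")
})

test_that("outlier exclusion only applies to the magnitude task", {
  s <- adaptrate:::new_obs_sequence(
    "probability", x = c(1, 0), h = c(0.5, 0.5), cp = c(FALSE, FALSE),
    config = probability_config(), seed = NA, "seq001")
  tr <- manual_trace(c(0.5, 0.2, 0.9)) # alpha_1 = -0.6; alpha_2 = -3.5
  lr <- compute_learning_rates(tr, s)
  expect_equal(lr$alpha[2], (0.9 - 0.2) / (0 - 0.2))
  expect_false(any(lr$excluded))
})

test_that("delta-rule cohorts yield a flat aligned curve at exactly alpha", {
  fx <- make_cohort_series("probability", "delta_rule", n_agents = 4,
                           n_seq = 12, n_sessions = 6, seed = 21, alpha = 0.35)
  dyn <- align_to_changepoints(fx$series)
  expect_equal(unname(dyn$mean_curve), rep(0.35, 10), tolerance = 1e-12)
  expect_equal(dyn$baseline, 0.35, tolerance = 1e-12)
  # identically zero differences: no clusters anywhere
  ct <- cluster_permutation_test(dyn, n_permutations = 200, seed = 1)
  expect_equal(nrow(ct$clusters), 0L)
})

test_that("alignment drops change points lacking two clean pre-change points", {
  # one subject, one session; cp at t=2 must be dropped, cp at t=6 kept
  alpha <- c(0.5, 0.2, 0.3, 0.4, 0.2, 0.9, 0.6, 0.5)
  cp <- c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  dyn <- align_to_changepoints(list(manual_series(alpha, cp)),
                               window = c(-2L, 2L))
  expect_equal(dyn$n_subjects, 1L)
  expect_equal(unname(dyn$mean_curve), c(0.4, 0.2, 0.9, 0.6))
  expect_equal(dyn$baseline, 0.3)
})

test_that("cluster p-values match exhaustive sign-flip enumeration", {
  set.seed(31)
  n <- 5
  M <- matrix(rnorm(n * 10, 0, 0.1), n, 10)
  M[, 3:5] <- M[, 3:5] + 0.25 # effect at offsets +1..+3
  dyn <- manual_dynamics(M)
  ct <- cluster_permutation_test(dyn, n_permutations = 10000, seed = 1)
  expect_true(ct$exact)
  # independent oracle: enumerate all 2^n sign assignments from scratch
  D <- M[, 3:10] - rowMeans(M[, 1:2])
  t_of <- function(Dm) {
    m <- colMeans(Dm)
    s <- apply(Dm, 2, sd)
    m / (s / sqrt(nrow(Dm)))
  }
  clusters_of <- function(Dm) {
    tv <- t_of(Dm)
    pv <- 2 * pt(-abs(tv), nrow(Dm) - 1)
    r <- rle(pv < 0.05)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    lapply(keep, function(k) {
      list(range = c(starts[k], ends[k]), stat = sum(abs(tv[starts[k]:ends[k]])))
    })
  }
  obs <- clusters_of(D)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null_max <- apply(signs, 1, function(e) {
    cl <- clusters_of(e * D)
    if (length(cl)) max(vapply(cl, `[[`, 0, "stat")) else 0
  })
  for (i in seq_along(obs)) {
    expect_equal(ct$clusters$p[i], mean(null_max >= obs[[i]]$stat),
                 tolerance = 1e-12)
  }
})

test_that("an injected effect is recovered as one cluster at those offsets", {
  set.seed(77)
  M <- matrix(rnorm(20 * 10, 0.3, 0.02), 20, 10)
  M[, 3:5] <- M[, 3:5] + 0.5 # offsets +1..+3
  ct <- cluster_permutation_test(manual_dynamics(M), n_permutations = 500,
                                 seed = 2)
  sig <- ct$clusters[ct$clusters$significant, ]
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$from_offset, 1L)
  expect_equal(sig$to_offset, 3L)
  expect_error(cluster_permutation_test(manual_dynamics(M),
                                        n_permutations = 50), "n_permutations")
})

test_that("estimate accuracy is exact for normative reporters and binned", {
  fx <- make_cohort_series("probability", "normative", n_agents = 3,
                           n_seq = 8, n_sessions = 4, seed = 41)
  acc <- estimate_accuracy(fx$cohort, fx$normative, n_bins = 6)
  expect_equal(acc$r_mean, 1, tolerance = 1e-12)
  expect_equal(nrow(acc$calibration), 6L)
  expect_equal(acc$calibration$subj_mean, acc$calibration$norm_mean,
               tolerance = 1e-12)
})

test_that("accuracy degrades monotonically with report noise", {
  seqs <- make_seq_set("probability", 8, seed = 43)
  nts <- lapply(seqs, normative_fit)
  r_at <- function(sd_level) {
    co <- simulate_cohort(seqs, 6, agent_config("report_noise",
                                                noise_sd = sd_level),
                          n_sessions = 6, seed = 5)
    estimate_accuracy(co, nts)$r_mean
  }
  r <- vapply(c(0.02, 0.1, 0.3), r_at, 0)
  expect_true(all(diff(r) < 0))
  expect_lt(r[2], 1)
})

test_that("constant traces are flagged as degenerate for accuracy", {
  seqs <- make_seq_set("probability", 2, seed = 44)
  nts <- lapply(seqs, normative_fit)
  flat <- manual_trace(rep(0.5, seqs[[1]]$n_obs + 1), sequence_id = "seq001")
  acc <- estimate_accuracy(list(flat), nts)
  expect_true(acc$per_subject$degenerate[1])
  expect_true(is.na(acc$per_subject$r[1]))
})

test_that("update-frequency statistics count gaps between report changes", {
  every <- manual_trace(c(0.5, cumsum(rep(0.001, 20)) + 0.5))
  st <- update_frequency_stats(list(every))
  expect_equal(st$frac_single, 1)
  expect_equal(st$mean_gap, 1)
  inc <- rep(0, 21)
  inc[seq(3, 21, by = 2)] <- 0.001 # moves at t = 2, 4, ..., 20 only
  alt <- manual_trace(0.5 + cumsum(inc))
  st2 <- update_frequency_stats(list(alt))
  expect_equal(st2$frac_single, 0)
  expect_equal(st2$mean_gap, 2)
  st3 <- update_frequency_stats(list(manual_trace(rep(0.5, 21))))
  expect_true(st3$degenerate)
  expect_true(is.na(st3$frac_single))
})
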