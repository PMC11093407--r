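# A fixed binary sequence wrapped as a probability-task obs_sequence.
wrap_binary <- function(x, id = "seq001") {
  adaptrate:::new_obs_sequence("probability", x, h = rep(0.5, length(x)),
                               cp = rep(FALSE, length(x)),
                               config = probability_config(), seed = NA,
                               sequence_id = id)
}

wrap_magnitude <- function(x, id = "seq001") {
  adaptrate:::new_obs_sequence("magnitude", x, h = rep(0.5, length(x)),
                               cp = rep(FALSE, length(x)),
                               config = magnitude_config(), seed = NA,
                               sequence_id = id)
}

test_that("first-observation estimate matches the truncated-uniform closed form", {
  # x = 1 on a uniform [0.1, 0.9] prior: posterior mean = E[h^2] / E[h]
  expected <- ((0.9^3 - 0.1^3) / 3 / 0.8) / ((0.9^2 - 0.1^2) / 2 / 0.8)
  tr <- run_probability_filter(wrap_binary(c(1, 0, 1)))
  expect_equal(tr$v[1], expected, tolerance = 1e-4)
  # and omega at t = 1 is the hazard (flagged initialization value)
  expect_equal(tr$omega[1], 1 / 20, tolerance = 1e-12)
})

test_that("with zero hazard the filter reduces to direct Bayes on the grid", {
  cfg <- probability_filter_config(hazard = 0)
  x <- c(1, 1, 0, 1, 0, 0, 1, 1, 1, 0)
  tr <- run_probability_filter(wrap_binary(x), cfg)
  g <- adaptrate:::filter_grid(cfg)
  direct <- rep(1 / length(g), length(g))
  for (t in seq_along(x)) {
    direct <- direct * (if (x[t] == 1) g else 1 - g)
    direct <- direct / sum(direct)
  }
  expect_lt(max(abs(tr$posterior - direct)), 1e-10)
  expect_equal(tr$v[length(x)], sum(g * direct), tolerance = 1e-10)
  expect_true(all(tr$omega == 0))
  # with no change-point mixing, predicted-prior and previous-posterior
  # uncertainties coincide
  expect_equal(tr$u, tr$u_prev, tolerance = 1e-12)
})

test_that("a long run of zeros drives the estimate to the lower support bound", {
  tr <- run_probability_filter(wrap_binary(rep(0, 200)),
                               probability_filter_config(hazard = 0))
  expect_lt(tr$v[200], 0.11)
})

test_that("filter posterior mean matches exhaustive change-point enumeration", {
  cfg <- probability_filter_config(hazard = 1 / 20, grid_size = 61L)
  g <- adaptrate:::filter_grid(cfg)
  # all 256 binary sequences of length 8
  grid8 <- as.matrix(expand.grid(rep(list(0:1), 8)))
  worst <- 0
  for (r in seq_len(nrow(grid8))) {
    x <- as.numeric(grid8[r, ])
    tr <- run_probability_filter(wrap_binary(x), cfg)
    v_oracle <- enum_posterior_mean(x, 1 / 20, g)
    worst <- max(worst, abs(tr$v[8] - v_oracle))
  }
  expect_lt(worst, 1e-6)
})

test_that("posterior mass stays normalized throughout filtering", {
  s <- generate_probability_sequence(seed = 4)
  tr <- run_probability_filter(s)
  expect_lt(abs(sum(tr$posterior) - 1), 1e-10)
  expect_true(all(tr$posterior >= 0))
  expect_true(all(tr$omega >= 0 & tr$omega <= 1))
  expect_true(all(tr$v >= 0.1 & tr$v <= 0.9))
})

test_that("non-binary observations are rejected by the filter", {
  bad <- wrap_binary(c(1, 0, 1))
  bad$x[2] <- 0.5
  expect_error(run_probability_filter(bad), "data error")
  sm <- generate_magnitude_sequence(seed = 1)
  expect_error(run_probability_filter(sm), "probability-task")
  expect_error(run_magnitude_model(generate_probability_sequence(seed = 1)),
               "magnitude-task")
})

test_that("reduced-model omega and eta match independent formula evaluation", {
  # one step from b = 0.5, tau = 0.2, N = 10/300, H = 0.1, x = 0.6
  N <- 10 / 300
  H <- 0.1
  tau <- 0.2
  b <- 0.5
  x <- 0.6
  sigma2 <- N^2 + tau * N^2 / (1 - tau)
  om_expected <- 1 * H / (1 * H + dnorm(x, b, sqrt(sigma2)) * (1 - H))
  eta_expected <- tau + (1 - tau) * om_expected
  tr <- run_magnitude_model(wrap_magnitude(x),
                            magnitude_model_config(b0 = 0.5, tau0 = 0.2))
  expect_equal(tr$omega[1], om_expected, tolerance = 1e-14)
  expect_equal(tr$eta[1], eta_expected, tolerance = 1e-14)
  expect_equal(tr$v[1], b + eta_expected * (x - b), tolerance = 1e-14)
  expect_equal(tr$u[1], sqrt(tau * sigma2), tolerance = 1e-14)
})

test_that("zero prediction error leaves the estimate unchanged and flags alpha", {
  tr <- run_magnitude_model(wrap_magnitude(c(0.5, 0.7)))
  expect_equal(tr$v[1], 0.5)
  expect_true(is.nan(tr$alpha[1]))
})

test_that("a huge surprise produces a one-shot reset (omega and eta near 1)", {
  tr <- run_magnitude_model(wrap_magnitude(c(0.5, 0.5, 0.99)),
                            magnitude_model_config(tau0 = 0.1))
  expect_gt(tr$omega[3], 0.999)
  expect_gt(tr$eta[3], 0.999)
  expect_equal(tr$v[3], 0.99, tolerance = 1e-2)
})

test_that("the measured learning rate reproduces the internal eta exactly", {
  for (seed in 1:5) {
    s <- generate_magnitude_sequence(seed = seed)
    tr <- run_magnitude_model(s)
    ok <- !is.nan(tr$alpha)
    expect_lt(max(abs(tr$alpha[ok] - tr$eta[ok])), 1e-10)
    expect_true(all(tr$sigma2 >= (10 / 300)^2))
    expect_true(all(tr$eta >= 0 & tr$eta <= 1))
  }
})

test_that("determinant variation ranges differ between tasks as predicted", {
  mag <- make_seq_set("magnitude", 30, seed = 5)
  prob <- make_seq_set("probability", 30, seed = 5)
  tr_m <- lapply(mag, normative_fit)
  tr_p <- lapply(prob, normative_fit)
  rng <- function(traces, f) {
    v <- unlist(lapply(traces, function(tr) tr[[f]][-1]))
    diff(range(v))
  }
  expect_gt(rng(tr_m, "omega"), rng(tr_p, "omega"))
  expect_gt(rng(tr_p, "u"), rng(tr_m, "u"))
})

test_that("determinant correlation is rank-invariant and validates input", {
  s <- generate_probability_sequence(seed = 8)
  tr <- run_probability_filter(s)
  # omega replaced by a strictly increasing function of |PE| => rho = 1
  v_prev <- c(0.5, tr$v[-tr$n_obs])
  tr$omega <- tanh(3 * abs(s$x - v_prev))
  expect_equal(measure_determinant_correlation(list(tr), list(s)), 1)
  expect_error(measure_determinant_correlation(list(), list()), "data error")
})

test_that("the filter converges with grid refinement", {
  s <- generate_probability_sequence(seed = 12)
  v_coarse <- run_probability_filter(s, probability_filter_config(grid_size = 301))$v
  v_fine <- run_probability_filter(s, probability_filter_config(grid_size = 602))$v
  expect_lt(max(abs(v_coarse - v_fine)), 1e-4)
})
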