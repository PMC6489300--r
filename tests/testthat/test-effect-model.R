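test_that("delta_bounds matches the closed form and its limits", {
  b <- delta_bounds(0.3, 0.09)
  expect_equal(b$lower, -0.2)
  expect_equal(b$upper, 0.6)
  # at the upper boundary the shifted mean has maximal variance == variance
  mu_shift <- 0.3 + b$upper
  expect_equal(mu_shift * (1 - mu_shift), 0.09)

  # variance near its 0.25 ceiling: the interval collapses around 0
  b2 <- delta_bounds(0.5, 0.25 - 1e-12)
  expect_lt(b2$upper - b2$lower, 1e-5)

  # variance -> 0: the full admissible shift range (-0.5, 0.5)
  b3 <- delta_bounds(0.5, 1e-12)
  expect_equal(b3$lower, -0.5, tolerance = 1e-5)
  expect_equal(b3$upper, 0.5, tolerance = 1e-5)

  expect_error(delta_bounds(0.5, 0.25), "0.25")
})

test_that("delta_bounds agrees with a grid-scan feasibility oracle", {
  set.seed(5)
  n <- 1000
  mu <- runif(n, 0.02, 0.98)
  v <- runif(n, 0.1, 0.9) * mu * (1 - mu)
  b <- delta_bounds(mu, v)
  for (i in sample(n, 50)) {
    grid <- seq(-mu[i] + 1e-6, 1 - mu[i] - 1e-6, length.out = 2001)
    feasible <- v[i] < (mu[i] + grid) * (1 - mu[i] - grid)
    inside <- grid > b$lower[i] & grid < b$upper[i]
    # grid points away from the boundary must agree exactly
    away <- abs(grid - b$lower[i]) > 2e-3 & abs(grid - b$upper[i]) > 2e-3
    expect_true(all(feasible[away] == inside[away]))
  }
})

test_that("sample_deltas respects truncation and symmetry", {
  pan <- wide_bounds_panel(1)
  d <- sample_deltas(rep(pan$mean, 1e5), rep(pan$variance, 1e5),
                     tau = 0.025, seed = 3)
  # symmetric bounds => zero mean within 3 SEs
  expect_lt(abs(mean(d)), 3 * 0.025 / sqrt(1e5))

  # draws stay strictly inside per-CpG bounds
  set.seed(8)
  mu <- runif(500, 0.05, 0.95)
  v <- runif(500, 0.05, 0.5) * mu * (1 - mu)
  b <- delta_bounds(mu, v)
  d2 <- sample_deltas(mu, v, tau = 0.2, seed = 4)
  expect_true(all(d2 > b$lower & d2 < b$upper))

  # tight bounds dominate any tau
  d3 <- sample_deltas(0.5 + numeric(1000), 0.2499999, tau = 5, seed = 5)
  expect_true(all(abs(d3) < 1e-3))
})

test_that("truncated draws match the analytic truncated-normal CDF", {
  # all CpGs share one bounds interval -> closed-form CDF
  pan <- wide_bounds_panel(1, var = 0.04)  # bounds (-0.3, 0.3)
  tau <- 0.15
  b <- delta_bounds(pan$mean, pan$variance)
  d <- sample_deltas(rep(pan$mean, 1e5), rep(pan$variance, 1e5), tau,
                     seed = 17)
  plo <- pnorm(b$lower, 0, tau)
  phi <- pnorm(b$upper, 0, tau)
  cdf <- function(x) (pnorm(x, 0, tau) - plo) / (phi - plo)
  xs <- seq(b$lower + 1e-6, b$upper - 1e-6, length.out = 200)
  ks <- max(abs(vapply(xs, function(x) mean(d <= x), numeric(1)) - cdf(xs)))
  expect_lt(ks, 0.01)
})

test_that("tau calibration hits the target window and is monotone", {
  pan <- wide_bounds_panel(200)
  # bounds never bind: calibrated tau ~ target / qnorm(0.99995)
  eff <- resolve_effect(pan, 10, target_delta = 0.05, p_cpgs = 2e4,
                        calib_reps = 10, seed = 2)
  expect_lt(abs(eff$achieved_q9999 - 0.05), 0.005)
  expect_lt(abs(eff$tau - 0.05 / qnorm(0.99995)), 0.002)

  eff2 <- resolve_effect(pan, 10, target_delta = 0.1, p_cpgs = 2e4,
                         calib_reps = 10, seed = 2)
  expect_gt(eff2$tau, eff$tau)  # monotone in the target

  # user-supplied tau passes through untouched
  eff3 <- resolve_effect(pan, 10, tau = 0.033, p_cpgs = 5e3,
                         calib_reps = 5, seed = 2)
  expect_equal(eff3$tau, 0.033)
  expect_true(is.na(eff3$target_delta))

  expect_error(resolve_effect(pan, 10, target_delta = 0.1, tau = 0.02),
               "exactly one")
  expect_error(resolve_effect(pan, 10), "exactly one")
})

test_that("calibration fails loudly when the target is unreachable", {
  # bounds confined to ~(-0.03, 0.03): a 0.4 target cannot be reached
  pan <- as_meth_panel(tibble::tibble(
    cpg_id = paste0("t", 1:50), mean = 0.5, variance = 0.249
  ), quiet = TRUE)
  expect_error(
    resolve_effect(pan, 5, target_delta = 0.4, p_cpgs = 2000,
                   calib_reps = 5, seed = 1),
    "calibration failed"
  )
})

test_that("compute_k inflates the target by the truly-DM fraction", {
  expect_identical(compute_k(2500, 0.8), 3125L)
  expect_identical(compute_k(2500, 1.0), 2500L)
  expect_identical(compute_k(2500, 0.625), 4000L)
  expect_error(compute_k(10, 0), "truly_dm_fraction > 0")
})

test_that("classify_truth implements the three-class taxonomy", {
  out <- classify_truth(c(0, 0.005, -0.02), detection_limit = 0.01)
  expect_equal(as.character(out), c("null", "negligible", "truly_dm"))
  # boundary: |delta| == limit counts as truly DM
  expect_equal(as.character(classify_truth(0.01)), "truly_dm")

  # tau -> 0 yields only negligible effects among shifted CpGs
  d <- sample_deltas(runif(200, 0.3, 0.7), rep(1e-3, 200), tau = 1e-4,
                     seed = 6)
  cls <- classify_truth(d)
  expect_equal(sum(cls == "truly_dm"), 0)
  expect_equal(sum(cls == "null"), 0)
})
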