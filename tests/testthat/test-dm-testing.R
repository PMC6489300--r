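test_that("m_transform is the base-2 logit with its symmetry", {
  expect_equal(m_transform(0.5), 0)
  expect_equal(m_transform(0.8), 2)
  expect_equal(m_transform(0.2), -2)
  b <- runif(20)
  expect_equal(m_transform(b), -m_transform(1 - b))
})

test_that("pooled t matches the closed form and t.test", {
  g1 <- matrix(c(1, 2, 3), nrow = 1)
  g2 <- matrix(c(4, 5, 6), nrow = 1)
  res <- methpower:::row_pooled_t(g1, g2)
  # t = -3 / sqrt(1 * (1/3 + 1/3)) = -3.674, df = 4
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$pvalue, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(res$pvalue,
               t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  # identical groups -> zero statistic -> p = 1
  same <- matrix(rnorm(8), nrow = 2)
  expect_equal(methpower:::row_pooled_t(same, same)$pvalue, c(1, 1))

  # constant unequal rows: pooled variance 0 but means differ -> p = 0
  res0 <- methpower:::row_pooled_t(matrix(1, 1, 3), matrix(2, 1, 3))
  expect_equal(res0$pvalue, 0)
  res1 <- methpower:::row_pooled_t(matrix(1, 1, 3), matrix(1, 1, 3))
  expect_equal(res1$pvalue, 1)
})

test_that("Welch t matches t.test on random rows", {
  set.seed(21)
  g1 <- matrix(rnorm(5 * 7), nrow = 5)
  g2 <- matrix(rnorm(5 * 9, sd = 2), nrow = 5)
  res <- methpower:::row_welch_t(g1, g2)
  ref <- vapply(1:5, function(i) t.test(g1[i, ], g2[i, ])$p.value,
                numeric(1))
  expect_equal(res$pvalue, ref, tolerance = 1e-12)
})

test_that("moderated t shrinks variances and reduces to pooled t at d0=0", {
  set.seed(22)
  g1 <- matrix(rnorm(200 * 6), nrow = 200)
  g2 <- matrix(rnorm(200 * 6), nrow = 200)
  mod0 <- methpower:::row_moderated_t(g1, g2, prior_df = 0)
  pooled <- methpower:::row_pooled_t(g1, g2)
  expect_equal(mod0$pvalue, pooled$pvalue, tolerance = 1e-12)

  mod <- methpower:::row_moderated_t(g1, g2)
  expect_gt(mod$d0, 0)
  # shrinkage pulls the extreme variances towards the prior
  sp2 <- ((6 - 1) * apply(g1, 1, var) + (6 - 1) * apply(g2, 1, var)) / 10
  post <- methpower:::squeeze_variances(sp2, 10)$var_post
  expect_lt(stats::var(log(post)), stats::var(log(sp2)))
})

test_that("moderated t agrees with the limma oracle", {
  set.seed(23)
  n1 <- 5; n2 <- 6
  m <- cbind(matrix(rnorm(500 * n1, sd = rep(runif(500, 0.5, 2), n1)),
                    nrow = 500),
             matrix(rnorm(500 * n2, sd = rep(runif(500, 0.5, 2), n2)),
                    nrow = 500))
  g1 <- m[, 1:n1]; g2 <- m[, n1 + 1:n2]
  mine <- methpower:::row_moderated_t(g1, g2)

  design <- cbind(1, rep(c(1, 0), c(n1, n2)))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(mine$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(mine$s02, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$pvalue, fit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("wilcoxon: exact enumeration, wilcox.test agreement, approx path", {
  # exact small-sample case: g1=(1,2), g2=(3,4) -> p = 1/3
  p <- methpower:::row_wilcoxon(matrix(c(1, 2), 1), matrix(c(3, 4), 1))
  expect_equal(p, 1 / 3)

  # enumeration oracle for all group sizes up to 4
  set.seed(24)
  for (n1 in 2:4) for (n2 in 2:4) {
    g1 <- matrix(rnorm(3 * n1), nrow = 3)
    g2 <- matrix(rnorm(3 * n2), nrow = 3)
    p <- methpower:::row_wilcoxon(g1, g2)
    ref <- vapply(1:3, function(i) wilcox_enum_oracle(g1[i, ], g2[i, ]),
                  numeric(1))
    expect_equal(p, ref, tolerance = 1e-12)
  }

  # exact path matches wilcox.test
  g1 <- matrix(rnorm(20 * 8), nrow = 20)
  g2 <- matrix(rnorm(20 * 9), nrow = 20)
  p <- methpower:::row_wilcoxon(g1, g2)
  ref <- vapply(1:20, function(i)
    wilcox.test(g1[i, ], g2[i, ], exact = TRUE)$p.value, numeric(1))
  expect_equal(p, ref, tolerance = 1e-12)

  # large-sample normal approximation with continuity correction
  g1 <- matrix(rnorm(10 * 30), nrow = 10)
  g2 <- matrix(rnorm(10 * 35, 0.5), nrow = 10)
  p <- methpower:::row_wilcoxon(g1, g2)
  ref <- vapply(1:10, function(i)
    wilcox.test(g1[i, ], g2[i, ], exact = FALSE, correct = TRUE)$p.value,
    numeric(1))
  expect_equal(p, ref, tolerance = 1e-10)

  # ties force the corrected approximation
  g1 <- matrix(rep(c(1, 2, 2, 3), 2), nrow = 2, byrow = TRUE)
  g2 <- matrix(rep(c(2, 3, 3, 4), 2), nrow = 2, byrow = TRUE)
  p <- methpower:::row_wilcoxon(g1, g2)
  ref <- suppressWarnings(wilcox.test(c(1, 2, 2, 3), c(2, 3, 3, 4),
                                      exact = FALSE)$p.value)
  expect_equal(p, rep(ref, 2), tolerance = 1e-10)
})

test_that("bh_adjust equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)

  set.seed(25)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("dm_test returns a coherent detection table", {
  pan <- test_panel(300)
  eff <- resolve_effect(pan, 15, target_delta = 0.2, p_cpgs = 1000,
                        calib_reps = 5, seed = 1)
  sim <- simulate_study(pan, eff, n_total = 60, p_cpgs = 300, seed = 2)
  for (m in c("limma", "cpgassoc", "ttest", "wilcoxon")) {
    res <- dm_test(sim, method = m, fdr_target = 0.05)
    expect_equal(nrow(res), 300)
    expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
    expect_true(all(res$qvalue >= res$pvalue))
    expect_identical(res$detected, res$qvalue < 0.05)
    expect_equal(res$delta, sim$delta)
  }
})

test_that("type I error is calibrated under the global null", {
  pan <- test_panel(4000, seed = 2)
  eff <- tibble::tibble(tau = 0.01, k = 0L, detection_limit = 0.01)
  sim <- simulate_study(pan, eff, n_total = 40, p_cpgs = 4000, seed = 9)
  tol <- 3 * sqrt(0.05 * 0.95 / 4000)
  for (m in c("limma", "cpgassoc", "ttest")) {
    p <- dm_test(sim, method = m)$pvalue
    expect_lt(abs(mean(p < 0.05) - 0.05), tol)
  }
})

test_that("power is monotone in effect size", {
  pan <- test_panel(1000)
  n_detect <- vapply(c(0.05, 0.3), function(tau) {
    eff <- resolve_effect(pan, 50, tau = tau, p_cpgs = 2000,
                          calib_reps = 3, seed = 1)
    sim <- simulate_study(pan, eff, n_total = 60, p_cpgs = 2000, seed = 3)
    res <- dm_test(sim, "limma")
    cc <- confusion_counts(res$detected, sim$truth)
    power_metrics(cc)$marginal_power
  }, numeric(1))
  expect_gt(n_detect[2], n_detect[1])
})
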