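test_that("DerSimonian-Laird tau2 matches the closed form", {
  # w = 10, 10; Q = 5; C = 20 - 200/20 = 10; tau2 = (5-1)/10
  expect_equal(estimate_tau2(c(0, 1), c(0.1, 0.1), "DL"), 0.4)
  # identical effects: Q = 0 in both methods
  expect_equal(estimate_tau2(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3), "DL"), 0)
  expect_equal(estimate_tau2(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3), "REML"), 0)
  expect_error(estimate_tau2(0.5, 0.1), "insufficient")
})

test_that("tau2 is location invariant and non-negative", {
  set.seed(21)
  for (i in 1:10) {
    y <- rnorm(8); v <- runif(8, 0.05, 0.3)
    for (m in c("DL", "REML")) {
      t1 <- estimate_tau2(y, v, m)
      expect_gte(t1, 0)
      expect_equal(estimate_tau2(y + 3.7, v, m), t1, tolerance = 1e-6)
    }
  }
})

test_that("tau2 estimates agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(22)
  y <- rnorm(15, 0.4, 0.5); v <- runif(15, 0.02, 0.4)
  expect_equal(estimate_tau2(y, v, "DL"),
               metafor::rma(y, v, method = "DL")$tau2, tolerance = 1e-6)
  expect_equal(estimate_tau2(y, v, "REML"),
               metafor::rma(y, v, method = "REML")$tau2, tolerance = 1e-5)
})

test_that("random-effects pooling matches formulas and limits", {
  # identical effects pool to themselves with fixed-effect precision
  p <- pool_random_effects(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.4))
  expect_equal(p$estimate, 0.3)
  expect_equal(p$i2, 0)
  expect_equal(p$se, sqrt(1 / sum(1 / c(0.1, 0.2, 0.4))))

  # hand case: symmetric weights
  p2 <- pool_random_effects(c(0, 1), c(0.1, 0.1), method = "DL")
  expect_equal(p2$estimate, 0.5)
  expect_equal(p2$tau2, 0.4)
  expect_equal(p2$i2, 80)

  # tau2 -> large: unweighted mean
  set.seed(23)
  y <- rnorm(6); v <- runif(6, 0.01, 1)
  p3 <- pool_random_effects(y, v, tau2 = 1e8)
  expect_equal(p3$estimate, mean(y), tolerance = 1e-6)

  # tau2 = 0 equals fixed-effect inverse-variance pooling (direct formula)
  p4 <- pool_random_effects(y, v, tau2 = 0)
  expect_equal(p4$estimate, sum(y / v) / sum(1 / v), tolerance = 1e-12)
  expect_equal(p4$se, sqrt(1 / sum(1 / v)), tolerance = 1e-12)
})

test_that("I2 lies in [0, 100] and is scale-free", {
  set.seed(24)
  for (i in 1:10) {
    y <- rnorm(7); v <- runif(7, 0.05, 0.5)
    p <- pool_random_effects(y, v)
    expect_gte(p$i2, 0); expect_lte(p$i2, 100)
    cc <- 3.1
    ps <- pool_random_effects(cc * y, cc^2 * v)
    expect_equal(ps$i2, p$i2, tolerance = 1e-10)
  }
})

test_that("Knapp-Hartung interval uses t quantiles and weighted residual scale", {
  set.seed(25)
  y <- rnorm(8, 0.5, 0.6); v <- runif(8, 0.05, 0.3)
  p <- pool_random_effects(y, v, method = "DL", ci_method = "knapp_hartung")
  w <- 1 / (v + p$tau2)
  se_kh <- sqrt(sum(w * (y - p$estimate)^2) / (7 * sum(w)))
  expect_equal(p$se, se_kh, tolerance = 1e-12)
  expect_equal(p$ci_high - p$estimate, qt(0.975, 7) * se_kh, tolerance = 1e-12)
  skip_if_not_installed("metafor")
  m <- metafor::rma(y, v, method = "DL", test = "knha")
  expect_equal(p$ci_low, m$ci.lb, tolerance = 1e-6)
  expect_equal(p$ci_high, m$ci.ub, tolerance = 1e-6)
})

test_that("binary meta-regression solves the weighted normal equations", {
  set.seed(26)
  for (i in 1:10) {
    n <- sample(3:5, 1)
    x <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    y <- rnorm(n); v <- runif(n, 0.05, 0.4)
    fit <- meta_regress_binary(y, v, x, method = "DL")
    ora <- wls_oracle(y, v, x, fit$tau2_residual)
    expect_equal(fit$intercept, ora$beta[1], tolerance = 1e-8)
    expect_equal(fit$slope, ora$beta[2], tolerance = 1e-8)
    expect_equal(fit$se_slope, sqrt(ora$vcov[2, 2]), tolerance = 1e-8)
  }
})

test_that("meta-regression slope equals the difference of subgroup weighted means when tau2 = 0", {
  y <- c(0.1, 0.3, 0.9, 1.1, 0.5)
  v <- c(0.1, 0.2, 0.1, 0.3, 0.2)
  x <- c(0, 0, 1, 1, 0)
  fit <- meta_regress_binary(y, v, x, method = "DL")
  if (fit$tau2_residual == 0) {
    w <- 1 / v
    m1 <- sum((w * y)[x == 1]) / sum(w[x == 1])
    m0 <- sum((w * y)[x == 0]) / sum(w[x == 0])
    expect_equal(fit$slope, m1 - m0, tolerance = 1e-10)
  }
  # shift invariance of the slope
  fit2 <- meta_regress_binary(y + 2, v, x, method = "DL")
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, fit$intercept + 2, tolerance = 1e-10)
  # label swap flips the sign
  fit3 <- meta_regress_binary(y, v, 1 - x, method = "DL")
  expect_equal(fit3$slope, -fit$slope, tolerance = 1e-10)
})

test_that("meta-regression agrees with metafor and rejects degenerate input", {
  skip_if_not_installed("metafor")
  set.seed(27)
  y <- rnorm(12, 0.4, 0.7); v <- runif(12, 0.03, 0.3); x <- rep(0:1, 6)
  for (m in c("DL", "REML")) {
    fit <- meta_regress_binary(y, v, x, method = m)
    ref <- metafor::rma(y, v, mods = ~x, method = m)
    expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(fit$se_slope, ref$se[2], tolerance = 1e-5)
    expect_equal(fit$tau2_residual, ref$tau2, tolerance = 1e-5)
  }
  expect_error(meta_regress_binary(y, v, rep(1, 12)), "no contrast")
  expect_error(meta_regress_binary(y[1:2], v[1:2], c(0, 1)), "insufficient")
  expect_error(meta_regress_binary(y, rep(0, 12), x), "zero")
})

test_that("cluster-robust se behaves correctly in degenerate and duplicated designs", {
  set.seed(28)
  y <- rnorm(14, 0.3, 0.5); v <- rep(0.1, 14); x <- rep(0:1, 7)
  fit <- meta_regress_binary(y, v, x, method = "DL")

  # every observation its own cluster, homoskedastic: CR2 ~ model se
  r <- robust_se(fit, seq_along(y), type = "CR2")
  expect_equal(r$se, fit$se_slope, tolerance = 0.15)
  expect_gt(r$df, 5)

  # duplicating rows within the same clusters: point estimate unchanged,
  # robust se must not shrink like independent replication would
  cl <- rep(1:7, each = 2)
  r1 <- robust_se(fit, cl, type = "CR2")
  fit2 <- meta_regress_binary(rep(y, 2), rep(v, 2), rep(x, 2),
                              method = "DL")
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-8)
  r2 <- robust_se(fit2, rep(cl, 2), type = "CR2")
  expect_gt(r2$se, r1$se / sqrt(2) * 1.2)

  expect_error(robust_se(fit, rep(1, 14)), "insufficient clusters")
})

test_that("CR0/CR1 scale as expected and CR1 tracks metafor's robust se", {
  skip_if_not_installed("metafor")
  set.seed(29)
  y <- rnorm(20, 0.3, 0.6); v <- runif(20, 0.05, 0.2)
  x <- rep(0:1, 10); cl <- rep(1:10, each = 2)
  fit <- meta_regress_binary(y, v, x, method = "REML")
  r0 <- robust_se(fit, cl, "CR0")
  r1 <- robust_se(fit, cl, "CR1")
  expect_equal(r1$se, r0$se * sqrt(10 / 9), tolerance = 1e-12)
  # metafor::robust uses an m/(m-p) type adjustment; same order of magnitude
  ref <- metafor::robust(metafor::rma(y, v, mods = ~x, method = "REML"),
                         cluster = cl)
  expect_equal(r1$se, ref$se[2], tolerance = 0.15)
})
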