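test_that("OLS fit matches hand normal equations and textbook cases", {
  f <- fit_ols(c(0, 1, 2), c(0, 1, 2))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r, 1)
  f2 <- fit_ols(c(0, 1, 2), c(0, 0, 3))
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, -0.5)
  set.seed(11)
  for (i in 1:20) {
    d <- rand_logpairs(n = sample(5:40, 1))
    f <- fit_ols(d$x, d$y)
    o <- ols_oracle(d$x, d$y)
    expect_equal(f$slope, o$slope, tolerance = 1e-12)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-12)
    expect_equal(f$slope_se, o$slope_se, tolerance = 1e-12)
    # closed-form identity: slope = r * sd(y) / sd(x)
    expect_equal(f$slope, f$r * sd(d$y) / sd(d$x), tolerance = 1e-12)
  }
  expect_error(fit_ols(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("SMA slope is the sd ratio and satisfies the OLS/r identity", {
  # perfect line: CI collapses onto the slope
  f <- fit_sma(1:5, 2 * (1:5))
  expect_equal(f$slope, 2)
  expect_equal(f$slope_ci, c(2, 2), tolerance = 1e-6)
  set.seed(12)
  for (i in 1:25) {
    d <- rand_logpairs(n = sample(5:60, 1), slope = runif(1, -3, 3))
    s <- fit_sma(d$x, d$y)
    o <- fit_ols(d$x, d$y)
    expect_equal(s$slope, sma_slope_oracle(d$x, d$y), tolerance = 1e-12)
    expect_equal(abs(s$slope), abs(o$slope) / abs(o$r), tolerance = 1e-12)
    expect_gte(abs(s$slope), abs(o$slope))
    expect_true(s$slope_ci[1] <= s$slope && s$slope <= s$slope_ci[2])
    expect_equal(s$slope_se, abs(s$slope) * sqrt((1 - s$r^2) / (s$n - 2)),
                 tolerance = 1e-12)
  }
})

test_that("SMA is symmetric under axis exchange and equivariant to rescaling", {
  set.seed(13)
  for (i in 1:10) {
    d <- rand_logpairs(n = 30)
    s_yx <- fit_sma(d$x, d$y)$slope
    s_xy <- fit_sma(d$y, d$x)$slope
    expect_equal(s_yx, 1 / s_xy, tolerance = 1e-12)
    c1 <- runif(1, 0.1, 10)
    expect_equal(fit_sma(d$x, c1 * d$y)$slope, c1 * s_yx, tolerance = 1e-12)
    expect_equal(fit_sma(c1 * d$x, d$y)$slope, s_yx / c1, tolerance = 1e-12)
  }
})

test_that("published OLS slope and correlation recover the SMA exponent", {
  expect_equal(sma_slope_from_ols(2.20, 0.8326), 2.20 / 0.8326)
  expect_lt(abs(sma_slope_from_ols(2.20, 0.8326) - 2.642), 0.001)
  expect_error(sma_slope_from_ols(2, 0), "nonzero")
  expect_error(sma_slope_from_ols(2, -0.5), "same sign")
})

test_that("two-group OLS interaction test behaves at its boundary cases", {
  x <- rep(seq(1, 2, length.out = 10), 2)
  g <- rep(c("a", "b"), each = 10)
  # identical noise-free lines: conventional null result
  t0 <- suppressWarnings(test_slope_heterogeneity_ols(x, 2 + 2.5 * x, g))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_equal(t0$df, 16)
  # a duplicated group compares a dataset against itself
  set.seed(14)
  y <- 2 + 2.5 * x[1:10] + rnorm(10, 0, 0.05)
  td <- test_slope_heterogeneity_ols(c(x[1:10], x[1:10]), c(y, y), g)
  expect_equal(td$statistic, 0, tolerance = 1e-8)
  # clearly different slopes are detected
  set.seed(15)
  xx <- runif(400, 1, 2)
  gg <- rep(c("a", "b"), each = 200)
  yy <- ifelse(gg == "a", 1 * xx, 3 * xx) + rnorm(400, 0, 0.05)
  expect_lt(test_slope_heterogeneity_ols(xx, yy, gg)$p_value, 1e-3)
  expect_error(test_slope_heterogeneity_ols(xx, yy, sample(letters[1:3], 400,
                                                           replace = TRUE)),
               "two groups")
})

test_that("common SMA slope pools degenerate and simulated groups correctly", {
  set.seed(16)
  d <- rand_logpairs(n = 30)
  own <- fit_sma(d$x, d$y)$slope
  # duplicated dataset as two groups: common slope is the dataset's own slope
  est <- estimate_common_slope_sma(c(d$x, d$x), c(d$y, d$y),
                                   rep(c("a", "b"), each = 30))
  expect_equal(est$common_slope, own, tolerance = 1e-9)
  # perfectly collinear data split in halves: the exact line slope
  xc <- seq(1, 2, length.out = 12); yc <- -1 + 2.7 * xc
  estc <- estimate_common_slope_sma(xc, yc, rep(c("a", "b"), 6))
  expect_equal(estc$common_slope, 2.7, tolerance = 1e-10)
  # parameter recovery at large n under a shared true slope
  cfg <- null_two_group_config(n = 3000L, b = 2.5)
  pop <- quiet_pop(cfg, seed = 21)
  g <- sub("_.*", "", pop$id)
  est2 <- estimate_common_slope_sma(log(pop$pronotum), log(pop$fresh_mass), g)
  expect_equal(est2$common_slope, 2.5, tolerance = 0.02)
  # opposite-sign correlations cannot share a slope sign
  set.seed(17)
  x2 <- rnorm(40); y2 <- c(2 * x2[1:20], -2 * x2[21:40]) + rnorm(40, 0, 0.1)
  expect_error(estimate_common_slope_sma(x2, y2, rep(c("a", "b"), each = 20)),
               "opposite sign")
})

test_that("common-slope likelihood ratio is exactly null for identical groups and detects different slopes", {
  set.seed(18)
  d <- rand_logpairs(n = 25)
  lr0 <- test_common_slope_sma(c(d$x, d$x), c(d$y, d$y),
                               rep(c("a", "b"), each = 25))
  expect_lt(lr0$statistic, 1e-10)
  expect_equal(lr0$p_value, 1, tolerance = 1e-6)
  expect_equal(lr0$df, 1)
  # groups generated with slopes 2 and 3 are separated decisively
  g2 <- data.frame(name = "g2", n = 200L, alpha = -2, mu_logL = 1.2,
                   sigma_logL = 0.06)
  g3 <- data.frame(name = "g3", n = 200L, alpha = -3, mu_logL = 1.2,
                   sigma_logL = 0.06)
  p2 <- quiet_pop(synth_config(g2, 2, 0.05, sqrt(0.05^2 + 0.02^2) / 2, 0.02),
                  seed = 19)
  p3 <- quiet_pop(synth_config(g3, 3, 0.05, sqrt(0.05^2 + 0.02^2) / 3, 0.02),
                  seed = 20)
  lr <- test_common_slope_sma(c(log(p2$pronotum), log(p3$pronotum)),
                              c(log(p2$fresh_mass), log(p3$fresh_mass)),
                              rep(c("b2", "b3"), each = 200))
  expect_lt(lr$p_value, 0.01)
  expect_gte(lr$statistic, 0)
})

test_that("one-sample SMA slope test is null at the fitted slope and decisive on exact lines", {
  set.seed(22)
  d <- rand_logpairs(n = 30)
  bhat <- fit_sma(d$x, d$y)$slope
  t0 <- test_sma_slope_value(d$x, d$y, bhat)
  expect_lt(abs(t0$statistic), 1e-10)
  expect_equal(t0$df, 28)
  xc <- seq(1, 2, length.out = 10)
  tc <- test_sma_slope_value(xc, 2 * xc, 3)
  expect_equal(tc$p_value, 0)
  expect_equal(test_sma_slope_value(xc, 2 * xc, 2)$p_value, 1)
})

test_that("one-sample SMA slope p-values rank-agree with a permutation oracle", {
  set.seed(23)
  d <- rand_logpairs(n = 8, slope = 2.5, noise = 0.15)
  b0s <- c(1.5, 2.2, 2.8, 4)
  p_t <- p_perm <- numeric(length(b0s))
  for (k in seq_along(b0s)) {
    p_t[k] <- test_sma_slope_value(d$x, d$y, b0s[k])$p_value
    u <- d$y - b0s[k] * d$x
    v <- d$y + b0s[k] * d$x
    obs <- abs(pearson_oracle(u, v))
    hits <- 0; nperm <- 2000
    for (j in 1:nperm)
      hits <- hits + (abs(pearson_oracle(u, sample(v))) >= obs)
    p_perm[k] <- hits / nperm
  }
  expect_identical(order(p_t), order(p_perm))
})

test_that("elevation test recovers pure shifts and is null for duplicated groups", {
  xc <- seq(1, 2, length.out = 10)
  # pure vertical offset, zero noise: the difference is exact and certain
  te <- test_elevation(c(xc, xc), c(2.5 * xc, 2.5 * xc + 0.3),
                       rep(c("lo", "hi"), each = 10), common_slope = 2.5)
  el <- te$group_elevations
  expect_equal(el$elevation[el$group == "hi"] - el$elevation[el$group == "lo"],
               0.3, tolerance = 1e-12)
  expect_equal(te$p_value, 0)
  set.seed(24)
  d <- rand_logpairs(n = 20)
  td <- test_elevation(c(d$x, d$x), c(d$y, d$y), rep(c("a", "b"), each = 20),
                       common_slope = 2.5)
  expect_equal(td$statistic, 0, tolerance = 1e-12)
  expect_error(test_elevation(d$x, d$y, rep(c("a", "b"), each = 10),
                              common_slope = NULL),
               "common slope")
})

test_that("slope z comparison matches the published-value arithmetic and is antisymmetric", {
  f1 <- list(slope = 2.642, slope_se = 0.11)
  f2 <- list(slope = 2.011, slope_se = 0.088)
  z <- compare_slopes_z(f1, f2)
  expect_equal(z$statistic, (2.642 - 2.011) / sqrt(0.11^2 + 0.088^2),
               tolerance = 1e-12)
  expect_equal(z$statistic, 4.479, tolerance = 1e-3)
  expect_lt(z$p_value, 0.001)
  zr <- compare_slopes_z(f2, f1)
  expect_equal(zr$statistic, -z$statistic)
  expect_equal(zr$p_value, z$p_value)
  z0 <- compare_slopes_z(f1, f1)
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p_value, 1)
  expect_error(compare_slopes_z(f1, list(slope = 2)), "slope_se")
})
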