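test_that("Bland-Altman handles identical inputs and constant offsets", {
  x <- c(8, 9, 10, 11, 12)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_difference, 0)
  expect_equal(ba0$sd_difference, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$mean_difference, -2)
  expect_equal(ba2$sd_difference, 0)
  expect_equal(ba2$trend_slope, 0)
  expect_error(bland_altman(1:4, 1:5), "paired")
})

test_that("Bland-Altman fields match hand arithmetic on a 5-pair toy set", {
  x <- c(10.0, 11.5, 9.0, 12.0, 10.5)
  y <- c(9.0, 12.5, 8.5, 10.0, 11.0)
  ba <- bland_altman(x, y)
  d <- x - y
  m <- (x + y) / 2
  md <- sum(d) / 5
  sdd <- sqrt(sum((d - md)^2) / 4)
  expect_equal(ba$mean_difference, md, tolerance = 1e-12)
  expect_equal(ba$sd_difference, sdd, tolerance = 1e-12)
  expect_equal(ba$loa_lower, md - 1.96 * sdd, tolerance = 1e-12)
  expect_equal(ba$loa_upper, md + 1.96 * sdd, tolerance = 1e-12)
  expect_equal(ba$pct_outside_loa,
               100 * mean(d < md - 1.96 * sdd | d > md + 1.96 * sdd))
  beta <- ols_normal_equations(m, d)
  expect_equal(ba$trend_slope, unname(beta["slope"]), tolerance = 1e-12)
})

test_that("calibration slope recovers identity and matches explicit formulas", {
  ei <- c(6, 7, 8, 9, 10, 11)
  ident <- calibration_slope(ei, ei)
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_true(ident$ci_lower <= 1 && 1 <= ident$ci_upper)

  tee <- c(8.1, 9.4, 8.9, 10.8, 10.2, 11.9)
  cal <- calibration_slope(ei, tee)
  beta <- ols_normal_equations(ei, tee)
  resid <- tee - beta["intercept"] - beta["slope"] * ei
  s2 <- sum(resid^2) / (6 - 2)
  se <- sqrt(s2 / sum((ei - mean(ei))^2))
  tq <- qt(0.975, 4)
  expect_equal(cal$slope, unname(beta["slope"]), tolerance = 1e-10)
  expect_equal(cal$ci_lower, unname(beta["slope"] - tq * se),
               tolerance = 1e-10)
  expect_equal(cal$ci_upper, unname(beta["slope"] + tq * se),
               tolerance = 1e-10)
  expect_error(calibration_slope(rep(8, 6), tee), "zero variance")
})

test_that("Wilcoxon signed-rank: degenerate case and exact enumeration oracle", {
  x <- c(5, 6, 7, 8)
  expect_true(paired_compare(x, x)$degenerate)

  set.seed(40)
  x <- round(rnorm(8, 10, 2), 3)
  y <- round(x + rnorm(8, 0.8, 1.1), 4)   # distinct, non-zero differences
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  res <- paired_compare(x, y)

  # enumerate the exact null distribution of V over all 2^8 sign assignments
  rk <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  v_null <- signs %*% rk
  v_obs <- sum(rk[d > 0])
  p_le <- mean(v_null <= v_obs)
  p_ge <- mean(v_null >= v_obs)
  expect_equal(res$statistic, v_obs)
  expect_equal(res$p_value, min(2 * min(p_le, p_ge), 1), tolerance = 1e-12)
})

test_that("correlations hit the perfect-agreement corners and the midrank oracle", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(correlate(x, x, "crude_spearman")$estimate, 1)
  expect_equal(correlate(x, -x, "crude_spearman")$estimate, -1)
  expect_equal(correlate(x, 2 * x + 1, "adjusted_pearson")$estimate, 1,
               tolerance = 1e-12)

  set.seed(3)
  a <- sample(rep(1:5, 2))        # heavy ties
  b <- a + sample(rep(0:1, 5))
  rho <- correlate(a, b, "crude_spearman")$estimate
  oracle <- cor(rank(a), rank(b), method = "pearson")
  expect_equal(rho, oracle, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("quantile bins split exact thirds and respect the lower-bin tie rule", {
  expect_equal(quantile_bins(1:9, 3), rep(1:3, each = 3))
  expect_warning(one <- quantile_bins(rep(4, 6), 3), "degenerate")
  expect_true(all(one == 1L))
  expect_error(quantile_bins(1:9, 1), "at least 2")

  # boundary-tied values must land in the lower bin
  v <- c(1, 2, 3, 3, 3, 4, 5, 6, 7, 8)
  br <- quantile(v, c(0, 0.5, 1), type = 7, names = FALSE)
  bins <- quantile_bins(v, 2)
  manual <- ifelse(v <= br[2], 1L, 2L)   # right-closed intervals
  expect_equal(bins, manual)
  expect_true(all(bins[v == br[2]] == 1L))
})

test_that("cross-classification counts agreement shares correctly", {
  ident <- cross_classify(rep(1:3, each = 5), rep(1:3, each = 5))
  expect_equal(ident$pct_same, 100)
  expect_equal(ident$kappa_weighted, 1)

  # balanced tertiles reversed: corners hold 2/3, the centre cell 1/3
  a <- rep(1:3, each = 3)
  rev_cc <- cross_classify(a, 4 - a)
  expect_equal(rev_cc$pct_opposite, 200 / 3, tolerance = 1e-12)
  expect_equal(rev_cc$pct_same, 100 / 3, tolerance = 1e-12)
  expect_equal(rev_cc$pct_same + rev_cc$pct_adjacent +
                 rev_cc$pct_intermediate + rev_cc$pct_opposite, 100,
               tolerance = 1e-9)
  expect_error(cross_classify(1:4, 1:3), "paired")
})

test_that("independent bins give near-zero weighted kappa at large n", {
  set.seed(77)
  n <- 100000
  cc <- cross_classify(sample(1:3, n, TRUE), sample(1:3, n, TRUE))
  expect_lt(abs(cc$kappa_weighted), 0.01)
})

test_that("weighted kappa: diagonal, antidiagonal and invariance properties", {
  expect_equal(weighted_kappa(diag(c(4, 9, 2))), 1)
  expect_equal(weighted_kappa(diag(c(4, 9, 2)), "quadratic"), 1)
  # balanced 2x2 cross table: complete disagreement
  expect_equal(weighted_kappa(matrix(c(0, 7, 7, 0), 2)), -1)
  set.seed(21)
  tab <- matrix(rpois(16, 6), 4)
  expect_equal(weighted_kappa(tab), weighted_kappa(17 * tab),
               tolerance = 1e-12)
  expect_equal(weighted_kappa(tab), kappa_naive(tab), tolerance = 1e-12)
  expect_equal(weighted_kappa(tab, "quadratic"),
               kappa_naive(tab, "quadratic"), tolerance = 1e-12)
  expect_error(weighted_kappa(matrix(0, 3, 3)), "empty")
})
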