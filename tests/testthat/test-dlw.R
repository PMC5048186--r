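test_that("elimination fit recovers an exact exponential", {
  t <- c(1, 3, 12, 14)
  fit <- fit_elimination(t, 1000 * exp(-0.1 * t), "h2")
  expect_equal(fit$k, 0.1, tolerance = 1e-12)
  expect_equal(fit$intercept_excess, 1000, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 4L)
})

test_that("two-point fit equals the closed-form rate", {
  e <- c(800, 35)
  t <- c(1, 14)
  fit <- fit_elimination(t, e, "o18")
  expect_equal(fit$k, log(e[1] / e[2]) / (t[2] - t[1]), tolerance = 1e-12)
})

test_that("elimination fit agrees with explicit normal equations", {
  set.seed(31)
  for (rep in 1:5) {
    t <- c(1, 3, 12, 14)
    e <- 900 * exp(-0.11 * t) * exp(rnorm(4, 0, 0.02))
    fit <- fit_elimination(t, e, "h2")
    beta <- ols_normal_equations(t, log(e))
    expect_equal(fit$k, -unname(beta["slope"]), tolerance = 1e-12)
    expect_equal(fit$intercept_excess, exp(unname(beta["intercept"])),
                 tolerance = 1e-12)
  }
})

test_that("non-positive enrichments are excluded, erroring below 2 points", {
  expect_warning(fit <- fit_elimination(c(1, 3, 12), c(500, -1, 100), "h2"),
                 "excluded")
  expect_equal(fit$n_points, 2L)
  expect_error(suppressWarnings(fit_elimination(c(1, 3), c(500, -1), "h2")),
               "at least 2")
})

test_that("fit is scale-equivariant and time-shift behaves as exp(k delta)", {
  t <- c(1, 3, 12, 14)
  set.seed(8)
  for (rep in 1:5) {
    e <- 700 * exp(-0.09 * t) * exp(rnorm(4, 0, 0.01))
    f0 <- fit_elimination(t, e, "h2")
    fs <- fit_elimination(t, 3.7 * e, "h2")
    expect_equal(fs$k, f0$k, tolerance = 1e-12)
    expect_equal(fs$intercept_excess, 3.7 * f0$intercept_excess,
                 tolerance = 1e-9)
    ft <- fit_elimination(t + 2, e, "h2")
    expect_equal(ft$k, f0$k, tolerance = 1e-12)
    expect_equal(ft$intercept_excess, f0$intercept_excess * exp(f0$k * 2),
                 tolerance = 1e-9)
  }
})

test_that("dilution space is linear in dose and inverse in intercept", {
  t <- c(1, 3, 12, 14)
  fit <- fit_elimination(t, 120 * exp(-0.12 * t), "o18")
  fit_half <- fit_elimination(t, 60 * exp(-0.12 * t), "o18")
  n1 <- compute_dilution_space(toy_dose(), fit)
  expect_equal(compute_dilution_space(toy_dose(dose_mass = 160), fit),
               2 * n1, tolerance = 1e-12)
  expect_equal(compute_dilution_space(toy_dose(), fit_half), 2 * n1,
               tolerance = 1e-10)
})

test_that("dilution space matches a hand-computed tracer-moles calculation", {
  t <- c(1, 3, 12, 14)
  fit_o <- fit_elimination(t, 20 * exp(-0.12 * t), "o18")
  fit_h <- fit_elimination(t, 80 * exp(-0.10 * t), "h2")
  dose <- toy_dose(dose_mass = 80)
  # by hand: 80 g x 0.10 = 8 g of 10% 18O water, M = 18.015 + 0.10 x 2.004
  mol_o18 <- 8 / (18.015 + 0.10 * 2.004) * 0.10
  expect_equal(compute_dilution_space(dose, fit_o), mol_o18 / 20e-6,
               tolerance = 1e-10)
  # 80 g x 0.05 = 4 g of 99.9% 2H water, two labelled positions per molecule
  mol_h2 <- 4 / (18.015 + 2 * 0.999 * 1.006) * 2 * 0.999
  expect_equal(compute_dilution_space(dose, fit_h), mol_h2 / (2 * 80e-6),
               tolerance = 1e-10)
})

test_that("TEE equals a hand-evaluated plug-in of the CO2/energy equations", {
  # construct exact exponentials with known rates and intercepts
  k_h <- 0.10; k_o <- 0.12
  t <- c(1, 3, 12, 14)
  dose <- toy_dose(dose_mass = 80)
  e0_h <- 70; e0_o <- 18
  samples <- data.frame(time = t,
                        h2_excess = e0_h * exp(-k_h * t),
                        o18_excess = e0_o * exp(-k_o * t))
  fit <- dlw_tee(samples, dose)

  mol_h2 <- 80 * 0.05 / (18.015 + 2 * 0.999 * 1.006) * 2 * 0.999
  mol_o18 <- 80 * 0.10 / (18.015 + 0.10 * 2.004) * 0.10
  n_h <- mol_h2 / (2 * e0_h * 1e-6)
  n_o <- mol_o18 / (e0_o * 1e-6)
  n_pool <- n_o / 1.01
  delta <- 1.007 * k_o - 1.041 * k_h
  r_co2 <- n_pool * delta / 2.078 - 0.0246 * 1.05 * n_pool * delta
  tee <- r_co2 * 22.414 * (1.106 + 3.941 / 0.85) * 4.184 / 1000

  expect_equal(fit$n_h, n_h, tolerance = 1e-10)
  expect_equal(fit$n_o, n_o, tolerance = 1e-10)
  expect_equal(fit$r_co2, r_co2, tolerance = 1e-9)
  expect_equal(fit$tee, tee, tolerance = 1e-9)
})

test_that("zero isotope turnover difference invalidates the TEE", {
  k_h <- 0.10
  k_o <- 1.041 * k_h / 1.007  # makes 1.007 k_O = 1.041 k_H exactly
  t <- c(1, 3, 12, 14)
  samples <- data.frame(time = t,
                        h2_excess = 70 * exp(-k_h * t),
                        o18_excess = 18 * exp(-k_o * t))
  fit <- dlw_tee(samples, toy_dose())
  expect_false(fit$valid)
  expect_true(is.na(fit$tee))
  expect_true("invalid_turnover" %in% fit$qc_flags)
})

test_that("engine round-trips the generator's true TEE without noise", {
  cfg <- make_cohort(n = 5, n_dlw = 5, seed = 19, noise = 0)
  coh <- generate_cohort(cfg)
  iso <- generate_isotope_series(coh$subjects, cfg)
  res <- dlw_cohort(iso$isotopes, iso$doses)
  expect_lt(max(abs(res$tee / coh$subjects$true_tee - 1)), 1e-3)
  expect_true(all(res$pool_ratio > 1.00 & res$pool_ratio < 1.07))
  expect_true(all(res$qc_flags == ""))
})

test_that("doubling true TEE doubles the fitted rate combination", {
  cfg <- make_cohort(n = 2, n_dlw = 1, seed = 3, noise = 0)
  coh <- generate_cohort(cfg)
  iso1 <- generate_isotope_series(coh$subjects, cfg)
  coh$subjects$true_tee <- 2 * coh$subjects$true_tee
  iso2 <- generate_isotope_series(coh$subjects, cfg)
  f1 <- dlw_tee(iso1$isotopes, iso1$doses)
  f2 <- dlw_tee(iso2$isotopes, iso2$doses)
  d1 <- 1.007 * f1$k_o - 1.041 * f1$k_h
  d2 <- 1.007 * f2$k_o - 1.041 * f2$k_h
  expect_equal(d2 / d1, 2, tolerance = 1e-9)
})

test_that("QC flags weight instability and diverging residuals", {
  k_h <- 0.10; k_o <- 0.12
  t <- c(1, 3, 12, 14)
  # intercepts chosen so the dilution-space ratio sits inside its QC window
  clean <- data.frame(time = t,
                      h2_excess = 79.4 * exp(-k_h * t) *
                        c(1.01, 0.99, 1.005, 0.995),
                      o18_excess = 18 * exp(-k_o * t) *
                        c(0.995, 1.005, 1.005, 0.995))
  fit <- dlw_tee(clean, toy_dose())
  expect_identical(fit$qc_flags, character(0))

  fit_w <- dlw_tee(clean, toy_dose(body_weight_pre = 80,
                                   body_weight_post = 81.5))
  expect_true("weight_unstable" %in% fit_w$qc_flags)

  bad <- clean
  bad$h2_excess[3] <- 5 * bad$h2_excess[3]
  fit_b <- dlw_tee(bad, toy_dose())
  expect_true("residual_outlier" %in% fit_b$qc_flags)

  # oracle: externally studentized residual computed from first principles
  y <- log(bad$h2_excess)
  X <- cbind(1, t)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  r <- y - H %*% y
  sse <- sum(r^2)
  i <- which.max(abs(r))
  s2_loo <- (sse - r[i]^2 / (1 - H[i, i])) / (4 - 2 - 1)
  t_i <- r[i] / sqrt(s2_loo * (1 - H[i, i]))
  expect_equal(max(abs(fit_b$fit_h$studentized)), abs(t_i),
               tolerance = 1e-10)
  expect_gt(abs(t_i), 3)
})

test_that("dlw_fit methods expose coefficients, predictions and residuals", {
  t <- c(1, 3, 12, 14)
  samples <- data.frame(time = t,
                        h2_excess = 70 * exp(-0.10 * t),
                        o18_excess = 18 * exp(-0.12 * t))
  fit <- dlw_tee(samples, toy_dose())
  expect_named(coef(fit), c("k_h", "k_o", "n_h", "n_o", "r_co2", "tee"))
  pr <- predict(fit, time = 0)
  expect_equal(pr$h2_excess, fit$fit_h$intercept_excess, tolerance = 1e-9)
  expect_equal(pr$o18_excess, fit$fit_o$intercept_excess, tolerance = 1e-9)
  res <- residuals(fit)
  expect_equal(nrow(res), 8L)
  expect_lt(max(abs(res$log_residual)), 1e-12)
  expect_output(print(fit), "TEE")
  expect_output(print(summary(fit)), "elimination")
})

test_that("TEE estimation is unbiased under 1% enrichment noise", {
  cfg0 <- make_cohort(n = 2, n_dlw = 1, seed = 101, noise = 0.01)
  coh <- generate_cohort(cfg0)
  truth <- coh$subjects$true_tee[1]
  errs <- vapply(1:200, function(i) {
    cfg <- make_cohort(n = 2, n_dlw = 1, seed = 101, noise = 0.01)
    cfg$seed <- 10000L + i   # reseed only the measurement noise
    iso <- generate_isotope_series(coh$subjects, cfg)
    dlw_tee(iso$isotopes, iso$doses)$tee / truth - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.005)
})
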