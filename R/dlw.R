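#' Physical constants and conventions for the DLW calculation
#'
#' Collects the constants of the two-pool multipoint doubly-labelled-water
#' calculation in one configurable place. CO2 production is
#' \deqn{rCO_2 = \frac{N}{2.078}(1.007 k_O - 1.041 k_H) - 0.0246\, r_{Gf},
#'   \quad r_{Gf} = 1.05\, N (1.007 k_O - 1.041 k_H)}
#' with `N` the body-water pool in mol, and energy expenditure follows the
#' Weir form `EE = VCO2 * (1.106 + 3.941/FQ)` kcal per litre of CO2.
#'
#' @param o_prop,h_prop proportionality factors applied to `k_O` and `k_H`.
#' @param dilution_divisor divisor of `N` in the CO2 equation (2.078).
#' @param fractionation_coef coefficient of the fractionated water loss term.
#' @param frac_water_loss fractionated water loss as a multiple of `N` times
#'   the rate difference (1.05).
#' @param o_pool_scale,h_pool_scale ratios of the 18O and 2H dilution spaces
#'   to the body-water pool; `N = n_O / o_pool_scale` by default
#'   (`pool_convention = "o18"`), or `n_H / h_pool_scale` when
#'   `pool_convention = "h2"`, or their mean when `"mean"`.
#' @param pool_convention which dilution space defines `N`.
#' @param food_quotient dietary food quotient converting CO2 to energy.
#' @param litres_per_mol molar volume of CO2 at STP (L/mol).
#' @param kj_per_kcal thermochemical calorie conversion.
#' @param water_molar_mass molar mass of body water (g/mol).
#' @param pool_ratio_window acceptable range of the dilution-space ratio
#'   `n_H / n_O` used as a technique quality check.
#' @param max_weight_change_kg acceptable study-period body-weight change.
#' @param studentized_threshold absolute externally studentized residual above
#'   which an elimination-curve point is flagged as diverging.
#' @return A list of class `"dlw_constants"`.
#' @export
dlw_constants <- function(o_prop = 1.007, h_prop = 1.041,
                          dilution_divisor = 2.078,
                          fractionation_coef = 0.0246,
                          frac_water_loss = 1.05,
                          o_pool_scale = 1.01, h_pool_scale = 1.04,
                          pool_convention = c("o18", "h2", "mean"),
                          food_quotient = 0.85,
                          litres_per_mol = 22.414,
                          kj_per_kcal = 4.184,
                          water_molar_mass = 18.015,
                          pool_ratio_window = c(1.00, 1.07),
                          max_weight_change_kg = 1.0,
                          studentized_threshold = 3.0) {
  pool_convention <- match.arg(pool_convention)
  if (food_quotient < 0.7 || food_quotient > 1.0)
    stop("food_quotient must lie in [0.7, 1.0]", call. = FALSE)
  structure(list(o_prop = o_prop, h_prop = h_prop,
                 dilution_divisor = dilution_divisor,
                 fractionation_coef = fractionation_coef,
                 frac_water_loss = frac_water_loss,
                 o_pool_scale = o_pool_scale, h_pool_scale = h_pool_scale,
                 pool_convention = pool_convention,
                 food_quotient = food_quotient,
                 litres_per_mol = litres_per_mol,
                 kj_per_kcal = kj_per_kcal,
                 water_molar_mass = water_molar_mass,
                 pool_ratio_window = pool_ratio_window,
                 max_weight_change_kg = max_weight_change_kg,
                 studentized_threshold = studentized_threshold),
            class = "dlw_constants")
}

# net mol CO2 per mol water pool per unit rate difference
co2_rate_factor <- function(cst) {
  1 / cst$dilution_divisor - cst$fractionation_coef * cst$frac_water_loss
}

# MJ of energy expenditure per mol CO2 at the configured food quotient
weir_mj_per_mol <- function(cst) {
  cst$litres_per_mol * (1.106 + 3.941 / cst$food_quotient) *
    cst$kj_per_kcal / 1000
}

# moles of excess tracer atoms administered with a dose
tracer_moles <- function(dose) {
  m_h <- 18.015 + 2 * dose$h2_purity * (2.014 - 1.008)
  m_o <- 18.015 + dose$o18_purity * (17.999 - 15.995)
  list(h2 = dose$dose_mass * dose$h2_fraction / m_h * 2 * dose$h2_purity,
       o18 = dose$dose_mass * dose$o18_fraction / m_o * dose$o18_purity)
}

#' Fit an isotope elimination curve
#'
#' Ordinary least squares of `log(excess enrichment)` on time — the
#' multipoint method. The elimination constant is minus the slope; the
#' zero-time intercept enrichment is the back-extrapolated plateau used for
#' the dilution-space calculation.
#'
#' @param time sampling times in days since dose (> 0, distinct).
#' @param excess enrichment above background (ppm); non-positive values are
#'   dropped with a warning.
#' @param isotope label, `"h2"` or `"o18"`.
#' @return A list of class `"elimination_fit"`: `isotope`, `k` (per day),
#'   `intercept_excess` (ppm), `r_squared`, `n_points`, `residuals`
#'   (log-scale), `studentized` (externally studentized residuals, `NA` when
#'   fewer than 4 points), and the underlying `lm` fit.
#' @examples
#' t <- c(1, 3, 12, 14)
#' fit <- fit_elimination(t, 1000 * exp(-0.1 * t), "h2")
#' c(fit$k, fit$intercept_excess)
#' @export
fit_elimination <- function(time, excess, isotope = c("h2", "o18")) {
  isotope <- match.arg(isotope)
  stopifnot(length(time) == length(excess))
  usable <- is.finite(time) & is.finite(excess) & excess > 0
  if (any(!usable))
    warning(sum(!usable), " sample(s) with non-positive excess excluded from ",
            isotope, " fit")
  time <- time[usable]; excess <- excess[usable]
  if (length(time) < 2L || length(unique(time)) < 2L)
    stop("need at least 2 usable samples at distinct times to fit ",
         isotope, " elimination", call. = FALSE)
  fit <- stats::lm(log(excess) ~ time)
  k <- -unname(stats::coef(fit)[2])
  res <- unname(stats::residuals(fit))
  # suppressWarnings: summary.lm warns on numerically perfect fits
  r2 <- if (length(time) > 2L) suppressWarnings(summary(fit)$r.squared) else 1
  # studentized residuals are meaningless on numerically perfect fits
  sigma <- sqrt(sum(res^2) / max(length(time) - 2L, 1L))
  stud <- if (length(time) < 4L) rep(NA_real_, length(time))
          else if (sigma < 1e-10) rep(0, length(time))
          else unname(stats::rstudent(fit))
  structure(list(isotope = isotope,
                 k = k,
                 intercept_excess = exp(unname(stats::coef(fit)[1])),
                 r_squared = r2,
                 n_points = length(time),
                 time = time,
                 excess = excess,
                 residuals = res,
                 studentized = stud,
                 lm = fit),
            class = "elimination_fit")
}

#' Isotope dilution space from dose and back-extrapolated enrichment
#'
#' The dilution space (pool size) is the moles of tracer administered divided
#' by the zero-time atom-fraction excess from the elimination fit; for 2H the
#' two hydrogen positions per water molecule are accounted for.
#'
#' @param dose one-row dose record (fields `dose_mass`, `h2_fraction`,
#'   `o18_fraction`, `h2_purity`, `o18_purity`).
#' @param fit an `"elimination_fit"`.
#' @return Dilution space in mol of water.
#' @export
compute_dilution_space <- function(dose, fit) {
  if (!is.finite(fit$intercept_excess) || fit$intercept_excess <= 0)
    stop("non-positive back-extrapolated intercept enrichment", call. = FALSE)
  stopifnot(dose$dose_mass > 0)
  mols <- tracer_moles(dose)
  frac_excess <- fit$intercept_excess * 1e-6
  if (fit$isotope == "h2") mols$h2 / (2 * frac_excess)
  else mols$o18 / frac_excess
}

#' Total energy expenditure from a doubly labelled water measurement
#'
#' The fitting function of the DLW engine. Fits both isotope elimination
#' curves, derives the dilution spaces, applies the two-pool CO2-production
#' equation and the Weir energy equation (see [dlw_constants()]), and
#' attaches quality-control flags (dilution-space ratio outside its window,
#' body-weight change beyond tolerance, diverging elimination-curve
#' residuals).
#'
#' @param samples data frame of enrichment samples for one subject with
#'   columns `time`, `h2_excess`, `o18_excess` (ppm above background).
#' @param dose one-row data frame with the dose record (`dose_mass`,
#'   `h2_fraction`, `o18_fraction`, `h2_purity`, `o18_purity`,
#'   `body_weight_pre`, `body_weight_post`).
#' @param constants a [dlw_constants()] object.
#' @return An object of class `"dlw_fit"` with components `subject_id`,
#'   `fit_h`, `fit_o` (the [fit_elimination()] results), `n_h`, `n_o`
#'   (dilution spaces, mol), `pool_ratio`, `k_h`, `k_o` (per day), `r_co2`
#'   (mol/d), `tee` (MJ/d, `NA` when the isotope turnover difference is not
#'   positive), `valid`, `qc_flags` and `constants`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()` and `plot()`.
#' @examples
#' cfg <- cohort_config(n_subjects = 2, n_dlw_subjects = 1, seed = 3,
#'                      enrichment_noise_sd = 0)
#' cohort <- generate_cohort(cfg)
#' iso <- generate_isotope_series(cohort$subjects, cfg)
#' fit <- dlw_tee(iso$isotopes, iso$doses)
#' fit$tee / cohort$subjects$true_tee[1]
#' @export
dlw_tee <- function(samples, dose, constants = dlw_constants()) {
  fit_h <- fit_elimination(samples$time, samples$h2_excess, "h2")
  fit_o <- fit_elimination(samples$time, samples$o18_excess, "o18")
  n_h <- compute_dilution_space(dose, fit_h)
  n_o <- compute_dilution_space(dose, fit_o)
  cst <- constants

  n_pool <- switch(cst$pool_convention,
                   o18 = n_o / cst$o_pool_scale,
                   h2 = n_h / cst$h_pool_scale,
                   mean = (n_o / cst$o_pool_scale + n_h / cst$h_pool_scale) / 2)
  delta <- cst$o_prop * fit_o$k - cst$h_prop * fit_h$k
  valid <- delta > 0
  r_co2 <- n_pool * delta * co2_rate_factor(cst)
  tee <- if (valid) r_co2 * weir_mj_per_mol(cst) else NA_real_

  obj <- structure(list(subject_id = if (!is.null(dose$subject_id))
                          dose$subject_id else NA_character_,
                        fit_h = fit_h, fit_o = fit_o,
                        n_h = n_h, n_o = n_o,
                        pool_ratio = n_h / n_o,
                        k_h = fit_h$k, k_o = fit_o$k,
                        r_co2 = r_co2, tee = tee,
                        valid = valid,
                        qc_flags = character(0),
                        dose = dose,
                        constants = cst),
                   class = "dlw_fit")
  qc_check(obj)
}

#' Quality-control checks for a DLW fit
#'
#' Re-evaluates the technique checks on a fitted result: the 2H:18O
#' dilution-space ratio must fall inside its window, body weight must be
#' stable over the study period, the rate-difference must be positive, and no
#' elimination-curve point may have an externally studentized log-scale
#' residual beyond the threshold.
#'
#' @param object a `"dlw_fit"`.
#' @param constants optionally override the thresholds in
#'   `object$constants`.
#' @return The object with its `qc_flags` (a character vector drawn from
#'   `"pool_ratio_out_of_range"`, `"weight_unstable"`, `"residual_outlier"`,
#'   `"invalid_turnover"`) updated.
#' @export
qc_check <- function(object, constants = NULL) {
  cst <- if (is.null(constants)) object$constants else constants
  flags <- character(0)
  w <- cst$pool_ratio_window
  if (object$pool_ratio < w[1] || object$pool_ratio > w[2])
    flags <- c(flags, "pool_ratio_out_of_range")
  d <- object$dose
  if (!is.null(d$body_weight_pre) && !is.null(d$body_weight_post) &&
      is.finite(d$body_weight_pre) && is.finite(d$body_weight_post) &&
      abs(d$body_weight_post - d$body_weight_pre) > cst$max_weight_change_kg)
    flags <- c(flags, "weight_unstable")
  stud <- c(object$fit_h$studentized, object$fit_o$studentized)
  if (any(abs(stud) > cst$studentized_threshold, na.rm = TRUE))
    flags <- c(flags, "residual_outlier")
  if (!object$valid)
    flags <- c(flags, "invalid_turnover")
  object$qc_flags <- flags
  object
}

#' @export
print.dlw_fit <- function(x, digits = 4, ...) {
  cat("Doubly labelled water fit")
  if (!is.na(x$subject_id)) cat(" - subject", x$subject_id)
  cat("\n")
  cat(sprintf("  k_H = %.*g /d, k_O = %.*g /d (n = %d samples)\n",
              digits, x$k_h, digits, x$k_o, x$fit_h$n_points))
  cat(sprintf("  dilution spaces: n_H = %.*g mol, n_O = %.*g mol (ratio %.3f)\n",
              digits, x$n_h, digits, x$n_o, x$pool_ratio))
  if (x$valid)
    cat(sprintf("  rCO2 = %.*g mol/d, TEE = %.*g MJ/d\n",
                digits, x$r_co2, digits, x$tee))
  else
    cat("  TEE invalid: non-positive isotope turnover difference\n")
  cat("  QC flags:",
      if (length(x$qc_flags)) paste(x$qc_flags, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' @export
summary.dlw_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dlw_fit")
}

#' @export
print.summary.dlw_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  for (fit in list(f$fit_h, f$fit_o)) {
    cat(sprintf("\n  %s elimination: intercept %.4g ppm, r^2 = %.6f\n",
                toupper(fit$isotope), fit$intercept_excess, fit$r_squared))
    tab <- data.frame(time = fit$time, excess = fit$excess,
                      log_residual = fit$residuals,
                      studentized = fit$studentized)
    print(tab, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
coef.dlw_fit <- function(object, ...) {
  c(k_h = object$k_h, k_o = object$k_o,
    n_h = object$n_h, n_o = object$n_o,
    r_co2 = object$r_co2, tee = object$tee)
}

#' Predicted enrichments from a DLW fit
#'
#' @param object a `"dlw_fit"`.
#' @param time days since dose at which to predict (defaults to the fitted
#'   sampling days).
#' @param ... unused.
#' @return Data frame with columns `time`, `h2_excess`, `o18_excess` (ppm).
#' @export
predict.dlw_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) time <- object$fit_h$time
  data.frame(time = time,
             h2_excess = object$fit_h$intercept_excess *
               exp(-object$k_h * time),
             o18_excess = object$fit_o$intercept_excess *
               exp(-object$k_o * time))
}

#' @export
residuals.dlw_fit <- function(object, ...) {
  data.frame(isotope = rep(c("h2", "o18"),
                           c(object$fit_h$n_points, object$fit_o$n_points)),
             time = c(object$fit_h$time, object$fit_o$time),
             log_residual = c(object$fit_h$residuals, object$fit_o$residuals))
}

#' @export
plot.dlw_fit <- function(x, ...) {
  t_all <- c(x$fit_h$time, x$fit_o$time)
  e_all <- c(x$fit_h$excess, x$fit_o$excess)
  graphics::plot(t_all, e_all, log = "y", type = "n",
                 xlab = "Days since dose",
                 ylab = "Excess enrichment (ppm)",
                 main = if (!is.na(x$subject_id))
                   paste("Isotope elimination -", x$subject_id)
                 else "Isotope elimination", ...)
  tt <- seq(min(t_all), max(t_all), length.out = 100)
  pr <- predict(x, tt)
  graphics::points(x$fit_h$time, x$fit_h$excess, pch = 16, col = "steelblue")
  graphics::lines(tt, pr$h2_excess, col = "steelblue")
  graphics::points(x$fit_o$time, x$fit_o$excess, pch = 17, col = "firebrick")
  graphics::lines(tt, pr$o18_excess, col = "firebrick")
  graphics::legend("topright", c(expression({}^2 * H), expression({}^18 * O)),
                   pch = c(16, 17), col = c("steelblue", "firebrick"),
                   bty = "n")
  invisible(x)
}

#' Run the DLW engine over a cohort
#'
#' Applies [dlw_tee()] to each subject present in an isotope table and
#' collects the results in one row per subject.
#'
#' @param isotopes data frame of enrichment samples (`subject_id`, `time`,
#'   `h2_excess`, `o18_excess`).
#' @param doses data frame of dose records, one row per subject.
#' @param constants a [dlw_constants()] object.
#' @return Data frame with columns `subject_id`, `k_h`, `k_o`, `n_h`, `n_o`,
#'   `pool_ratio`, `r_co2`, `tee`, `r_squared_h`, `r_squared_o`, `qc_flags`
#'   (comma-separated, empty when clean).
#' @export
dlw_cohort <- function(isotopes, doses, constants = dlw_constants()) {
  rows <- lapply(doses$subject_id, function(id) {
    fit <- dlw_tee(isotopes[isotopes$subject_id == id, , drop = FALSE],
                   doses[doses$subject_id == id, , drop = FALSE],
                   constants)
    data.frame(subject_id = id,
               k_h = fit$k_h, k_o = fit$k_o,
               n_h = fit$n_h, n_o = fit$n_o,
               pool_ratio = fit$pool_ratio,
               r_co2 = fit$r_co2, tee = fit$tee,
               r_squared_h = fit$fit_h$r_squared,
               r_squared_o = fit$fit_o$r_squared,
               qc_flags = paste(fit$qc_flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
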