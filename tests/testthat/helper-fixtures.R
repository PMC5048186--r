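# shared fixtures: small cohorts and hand-rolled oracles used across files

make_cohort <- function(n = 10, n_dlw = 4, seed = 11, noise = 0, ...) {
  cohort_config(n_subjects = n, n_dlw_subjects = n_dlw, seed = seed,
                enrichment_noise_sd = noise, ...)
}

# a plain dose record with convenient round numbers
toy_dose <- function(dose_mass = 80, h2_fraction = 0.05, o18_fraction = 0.10,
                     h2_purity = 0.999, o18_purity = 0.10,
                     body_weight_pre = 80, body_weight_post = 80) {
  data.frame(subject_id = "T1", body_weight_pre = body_weight_pre,
             body_weight_post = body_weight_post, dose_mass = dose_mass,
             h2_fraction = h2_fraction, o18_fraction = o18_fraction,
             h2_purity = h2_purity, o18_purity = o18_purity,
             stringsAsFactors = FALSE)
}

# independent OLS via explicit normal equations (no lm)
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# naive double-loop weighted kappa, written independently of the package
kappa_naive <- function(tab, scheme = "linear") {
  tab <- as.matrix(tab)
  k <- nrow(tab)
  n <- sum(tab)
  rm_ <- rowSums(tab) / n
  cm_ <- colSums(tab) / n
  num <- 0; den <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    w <- abs(i - j) / (k - 1)
    if (scheme == "quadratic") w <- w^2
    num <- num + w * tab[i, j] / n
    den <- den + w * rm_[i] * cm_[j]
  }
  1 - num / den
}
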