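#' Configuration for a synthetic validation cohort
#'
#' Builds and validates the parameter set that drives [generate_cohort()] and
#' [generate_isotope_series()]. Defaults reproduce the structure of a
#' middle-aged validation cohort: 200 subjects reporting intake with two
#' instruments (a short food record, `"record"`, and a food-frequency
#' questionnaire, `"ffq"`), of whom 40 also undergo a 14-day doubly labelled
#' water (DLW) protocol. True total energy expenditure (TEE) averages
#' 10.8 MJ/d; mean reporting accuracy (EI:TEE) is 80% for the record and 82%
#' for the FFQ with SDs of 23% and 33%.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_dlw_subjects number of subjects with DLW measurements
#'   (must not exceed `n_subjects`).
#' @param seed integer master seed; the whole cohort is reproducible from it.
#' @param tee_mean,tee_sd mean and SD of true TEE (MJ/d). The default SD is
#'   back-calculated from a 95% CI of the mean (9.9, 11.6) at n = 40.
#' @param accuracy_mean,accuracy_sd named numeric vectors (per instrument) of
#'   the mean and SD of the reporting-accuracy ratio EI:TEE. Accuracy is drawn
#'   from a normal truncated at zero.
#' @param cv_within_ei within-subject CV (percent) of record-reported energy.
#' @param cv_within_ffq within-subject CV (percent) of FFQ-reported energy
#'   (default 0: the FFQ reflects habitual intake over months).
#' @param cv_within_tee within-subject CV (percent) of TEE over the 2-week
#'   protocol; used downstream for Goldberg cut-offs, not for simulation noise.
#' @param macronutrient_share_means named fractions of reported energy from
#'   protein, fat, carbohydrate and alcohol; must sum to 1.
#' @param share_jitter_sd log-scale SD of per-subject jitter applied to the
#'   energy shares before renormalisation.
#' @param energy_factors named energy conversion factors (kJ/g) used to
#'   back-calculate macronutrient grams from energy shares.
#' @param fat_sub_shares fractions of fat grams that are SFA, MUFA and PUFA
#'   (their sum must be at most 1; the remainder is the glycerol backbone).
#' @param sucrose_share fraction of carbohydrate grams that is sucrose.
#' @param fibre_density fibre intake in g per MJ of reported energy.
#' @param enrichment_noise_sd relative SD of multiplicative measurement noise
#'   on isotope enrichments (0.01 = 1%).
#' @param sample_days post-dose urine sampling days (strictly increasing, > 0).
#' @param tbw_fraction named total-body-water fractions of body weight per sex.
#' @param dose_g_per_kg DLW dose in g per kg body weight; reduced for subjects
#'   with BMI above `obese_bmi` to `dose_g_per_kg_obese` (per sex).
#' @param obese_bmi BMI threshold (kg/m^2) above which the reduced dose applies.
#' @param dose_g_per_kg_obese named per-sex reduced doses (g/kg).
#' @param h2_fraction,o18_fraction mass fractions of 2H-labelled and
#'   18O-labelled water in the dose mixture.
#' @param h2_purity,o18_purity isotopic atom fractions of the labelled waters.
#' @param ko_kh_ratio ratio k_O / k_H used to split the fitted rate difference
#'   into individual elimination constants when constructing isotope curves.
#' @param food_quotient dietary food quotient used in the energy equation.
#' @param weight_change_sd SD (kg) of simulated study-period weight change,
#'   clipped to `weight_change_max`.
#' @param weight_change_max maximum absolute simulated weight change (kg).
#'
#' @return A validated list of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_subjects = 20, n_dlw_subjects = 5, seed = 1)
#' cohort <- generate_cohort(cfg)
#' head(cohort$subjects)
#' @export
cohort_config <- function(n_subjects = 200L,
                          n_dlw_subjects = 40L,
                          seed = 1L,
                          tee_mean = 10.8,
                          tee_sd = 2.7,
                          accuracy_mean = c(record = 0.80, ffq = 0.82),
                          accuracy_sd = c(record = 0.23, ffq = 0.33),
                          cv_within_ei = 20.6,
                          cv_within_ffq = 0,
                          cv_within_tee = 8.4,
                          macronutrient_share_means = c(protein = 0.17,
                                                        fat = 0.34,
                                                        carbohydrate = 0.45,
                                                        alcohol = 0.04),
                          share_jitter_sd = 0.10,
                          energy_factors = c(protein = 17, fat = 37,
                                             carbohydrate = 17, alcohol = 29),
                          fat_sub_shares = c(sfa = 0.42, mufa = 0.38,
                                             pufa = 0.16),
                          sucrose_share = 0.20,
                          fibre_density = 2.0,
                          enrichment_noise_sd = 0.01,
                          sample_days = c(1, 3, 12, 14),
                          tbw_fraction = c(female = 0.50, male = 0.58),
                          dose_g_per_kg = 1.0,
                          obese_bmi = 30,
                          dose_g_per_kg_obese = c(female = 0.5, male = 0.6),
                          h2_fraction = 0.05,
                          o18_fraction = 0.10,
                          h2_purity = 0.999,
                          o18_purity = 0.10,
                          ko_kh_ratio = 1.25,
                          food_quotient = 0.85,
                          weight_change_sd = 0.3,
                          weight_change_max = 1.0) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_dlw_subjects = as.integer(n_dlw_subjects),
              seed = as.integer(seed),
              tee_mean = tee_mean, tee_sd = tee_sd,
              accuracy_mean = accuracy_mean, accuracy_sd = accuracy_sd,
              cv_within_ei = cv_within_ei, cv_within_ffq = cv_within_ffq,
              cv_within_tee = cv_within_tee,
              macronutrient_share_means = macronutrient_share_means,
              share_jitter_sd = share_jitter_sd,
              energy_factors = energy_factors,
              fat_sub_shares = fat_sub_shares,
              sucrose_share = sucrose_share,
              fibre_density = fibre_density,
              enrichment_noise_sd = enrichment_noise_sd,
              sample_days = sample_days,
              tbw_fraction = tbw_fraction,
              dose_g_per_kg = dose_g_per_kg,
              obese_bmi = obese_bmi,
              dose_g_per_kg_obese = dose_g_per_kg_obese,
              h2_fraction = h2_fraction, o18_fraction = o18_fraction,
              h2_purity = h2_purity, o18_purity = o18_purity,
              ko_kh_ratio = ko_kh_ratio,
              food_quotient = food_quotient,
              weight_change_sd = weight_change_sd,
              weight_change_max = weight_change_max)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L)
  if (cfg$n_dlw_subjects > cfg$n_subjects)
    stop("n_dlw_subjects must not exceed n_subjects", call. = FALSE)
  if (cfg$tee_sd < 0 || any(cfg$accuracy_sd < 0))
    stop("standard deviations must be non-negative", call. = FALSE)
  if (cfg$tee_mean <= 0)
    stop("tee_mean must be positive", call. = FALSE)
  if (abs(sum(cfg$macronutrient_share_means) - 1) > 1e-9)
    stop("macronutrient share means must sum to 1", call. = FALSE)
  need <- c("protein", "fat", "carbohydrate", "alcohol")
  if (!all(need %in% names(cfg$macronutrient_share_means)) ||
      !all(need %in% names(cfg$energy_factors)))
    stop("shares and energy factors need names: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (sum(cfg$fat_sub_shares) > 1 + 1e-9)
    stop("fat sub-shares (sfa, mufa, pufa) must sum to at most 1",
         call. = FALSE)
  d <- cfg$sample_days
  if (length(d) < 2L || d[1] <= 0 || any(diff(d) <= 0))
    stop("sample_days must be strictly increasing and start after day 0",
         call. = FALSE)
  if (cfg$cv_within_ei < 0 || cfg$cv_within_tee < 0 || cfg$cv_within_ffq < 0)
    stop("within-subject CVs must be non-negative", call. = FALSE)
  if (!all(c("record", "ffq") %in% names(cfg$accuracy_mean)))
    stop("accuracy_mean needs entries for 'record' and 'ffq'", call. = FALSE)
  invisible(cfg)
}

# normal truncated at zero; simple rejection (truncation mass is tiny for the
# accuracy distributions used here)
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate a synthetic validation cohort
#'
#' Draws subjects (sex, anthropometry, true TEE, study-period weight change)
#' and per-instrument reported intakes. Reported energy is
#' `true_tee * accuracy * within-subject noise`, with accuracy drawn from a
#' normal truncated at zero (instrument-specific mean/SD) and noise a
#' truncated normal multiplier with the configured within-subject CV.
#' Macronutrient grams are back-calculated from reported energy through
#' per-subject jittered energy shares and standard energy conversion factors,
#' so energy and macronutrients are exactly consistent by construction.
#'
#' The generator is fully deterministic for a fixed `config$seed`.
#'
#' @param config a [cohort_config()] object.
#' @return A list of class `"synthetic_cohort"` with data frames
#'   `subjects` (one row per subject: `id`, `sex`, `height`, `body_weight`,
#'   `bmi`, `true_tee`, `weight_change`, `dlw`) and `intakes` (one row per
#'   subject x instrument: energy in MJ/d, macronutrients and fibre in g/d),
#'   plus the `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 10, n_dlw_subjects = 4,
#'                                         seed = 7))
#' with(subset(cohort$intakes, instrument == "record"),
#'      mean(energy / cohort$subjects$true_tee))
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_subjects

  sex <- rep(c("female", "male"), length.out = n)
  height <- ifelse(sex == "female",
                   stats::rnorm(n, 1.66, 0.06),
                   stats::rnorm(n, 1.80, 0.07))
  bmi <- rnorm_pos(n, 26.5, 3.8)
  body_weight <- bmi * height^2
  true_tee <- rnorm_pos(n, config$tee_mean, config$tee_sd)
  weight_change <- pmin(pmax(stats::rnorm(n, 0, config$weight_change_sd),
                             -config$weight_change_max),
                        config$weight_change_max)
  dlw <- seq_len(n) <= config$n_dlw_subjects

  subjects <- data.frame(id = sprintf("S%03d", seq_len(n)),
                         sex = sex,
                         height = height,
                         body_weight = body_weight,
                         bmi = bmi,
                         true_tee = true_tee,
                         weight_change = weight_change,
                         dlw = dlw,
                         stringsAsFactors = FALSE)

  intakes <- do.call(rbind, lapply(c("record", "ffq"), function(instr) {
    acc <- rnorm_pos(n, config$accuracy_mean[[instr]],
                     config$accuracy_sd[[instr]])
    cv <- if (instr == "record") config$cv_within_ei else config$cv_within_ffq
    noise <- rnorm_pos(n, 1, cv / 100)
    energy <- true_tee * acc * noise
    macro_grams(subjects$id, instr, energy, config)
  }))
  rownames(intakes) <- NULL

  out <- list(subjects = subjects, intakes = intakes, config = config)
  class(out) <- "synthetic_cohort"
  out
}

# back-calculate macronutrient grams from reported energy via jittered shares
macro_grams <- function(ids, instrument, energy, config) {
  n <- length(energy)
  mu <- config$macronutrient_share_means
  shares <- vapply(mu, function(m)
    m * exp(stats::rnorm(n, 0, config$share_jitter_sd)), numeric(n))
  if (n == 1L) shares <- matrix(shares, nrow = 1,
                                dimnames = list(NULL, names(mu)))
  shares <- shares / rowSums(shares)
  kj <- energy * 1000
  grams <- sweep(sweep(shares, 1, kj, "*"), 2,
                 config$energy_factors[colnames(shares)], "/")
  fat <- grams[, "fat"]
  fs <- config$fat_sub_shares
  carb <- grams[, "carbohydrate"]
  data.frame(subject_id = ids,
             instrument = instrument,
             energy = energy,
             protein = grams[, "protein"],
             fat = fat,
             sfa = fat * fs[["sfa"]],
             mufa = fat * fs[["mufa"]],
             pufa = fat * fs[["pufa"]],
             carbohydrate = carb,
             sucrose = carb * config$sucrose_share,
             fibre = config$fibre_density * energy,
             alcohol = grams[, "alcohol"],
             stringsAsFactors = FALSE)
}

#' Generate doubly labelled water dose records and enrichment series
#'
#' For each DLW subject, constructs a dose record following the dosing
#' protocol (1 g DLW/kg body weight, reduced to 0.6 g/kg for men and
#' 0.5 g/kg for women with BMI above 30 kg/m^2) and a urine enrichment time
#' series. Pool sizes derive from body weight via per-sex total-body-water
#' fractions (the 18O and 2H dilution spaces exceed body water by the usual
#' 1% and 4% exchange factors). The elimination constants `k_O` and `k_H` are
#' constructed by inverting the CO2-production equation used by [dlw_tee()],
#' so that with noise-free enrichments the engine recovers `true_tee`
#' exactly; their ratio is fixed at `config$ko_kh_ratio`. Enrichments decay
#' single-exponentially from the dose-determined intercept and are observed
#' with multiplicative truncated-normal noise of relative SD
#' `config$enrichment_noise_sd`.
#'
#' @param subjects a data frame of subjects as produced by
#'   [generate_cohort()] (rows with `dlw = FALSE` are skipped), or a
#'   single-row subset.
#' @param config the [cohort_config()] used to generate the cohort.
#' @return A list with data frames `doses` (one row per DLW subject) and
#'   `isotopes` (one row per subject x sampling day with `h2_excess` and
#'   `o18_excess` in ppm above background).
#' @export
generate_isotope_series <- function(subjects, config) {
  validate_cohort_config(config)
  set.seed(config$seed + 1L)
  if (!is.null(subjects$dlw)) subjects <- subjects[subjects$dlw, , drop = FALSE]
  stopifnot(nrow(subjects) >= 1L, all(subjects$true_tee > 0))

  doses <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    gkg <- if (s$bmi > config$obese_bmi)
      config$dose_g_per_kg_obese[[s$sex]] else config$dose_g_per_kg
    data.frame(subject_id = s$id,
               body_weight_pre = s$body_weight,
               body_weight_post = s$body_weight + s$weight_change,
               dose_mass = gkg * s$body_weight,
               h2_fraction = config$h2_fraction,
               o18_fraction = config$o18_fraction,
               h2_purity = config$h2_purity,
               o18_purity = config$o18_purity,
               stringsAsFactors = FALSE)
  }))

  isotopes <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    d <- doses[i, ]
    kin <- isotope_kinetics(s, d, config)
    t <- config$sample_days
    nh <- length(t)
    noise_h <- rnorm_pos(nh, 1, config$enrichment_noise_sd)
    noise_o <- rnorm_pos(nh, 1, config$enrichment_noise_sd)
    data.frame(subject_id = s$id,
               time = t,
               h2_excess = kin$e0_h * exp(-kin$k_h * t) * noise_h,
               o18_excess = kin$e0_o * exp(-kin$k_o * t) * noise_o,
               stringsAsFactors = FALSE)
  }))
  rownames(doses) <- rownames(isotopes) <- NULL
  list(doses = doses, isotopes = isotopes)
}

# invert the engine's forward model: intercepts from dose and pool sizes,
# rate constants from the target TEE
isotope_kinetics <- function(subject, dose, config) {
  cst <- dlw_constants(food_quotient = config$food_quotient)
  tbw_kg <- config$tbw_fraction[[subject$sex]] * subject$body_weight
  n_mol <- tbw_kg * 1000 / cst$water_molar_mass
  n_h <- cst$h_pool_scale * n_mol   # 2H dilution space
  n_o <- cst$o_pool_scale * n_mol   # 18O dilution space

  mols <- tracer_moles(dose)
  e0_h <- mols$h2 / (2 * n_h) * 1e6   # ppm atom-fraction excess
  e0_o <- mols$o18 / n_o * 1e6

  # TEE -> rCO2 -> rate-difference, with N as the engine will compute it
  r_co2 <- subject$true_tee / weir_mj_per_mol(cst)
  delta <- r_co2 / (n_mol * co2_rate_factor(cst))
  k_h <- delta / (1.007 * config$ko_kh_ratio - 1.041)
  if (k_h <= 0) stop("ko_kh_ratio too small: implied k_h not positive",
                     call. = FALSE)
  list(e0_h = e0_h, e0_o = e0_o, k_h = k_h, k_o = config$ko_kh_ratio * k_h)
}

#' Write or read cohort tables as delimited text
#'
#' `write_cohort()` writes `subjects.csv`, `intakes.csv` and — when isotope
#' data are supplied — `doses.csv` and `isotopes.csv` to a directory, plus a
#' `metadata.json` sidecar recording the seed and generator parameters.
#' `read_cohort()` reads them back.
#'
#' @param cohort a `"synthetic_cohort"` from [generate_cohort()].
#' @param isotope_data optional list from [generate_isotope_series()].
#' @param dir output (input) directory; created if missing.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   list of the data frames found.
#' @export
write_cohort <- function(cohort, dir, isotope_data = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$intakes, file.path(dir, "intakes.csv"),
                   row.names = FALSE)
  if (!is.null(isotope_data)) {
    utils::write.csv(isotope_data$doses, file.path(dir, "doses.csv"),
                     row.names = FALSE)
    utils::write.csv(isotope_data$isotopes, file.path(dir, "isotopes.csv"),
                     row.names = FALSE)
  }
  meta <- unclass(cohort$config)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- c(subjects = "subjects.csv", intakes = "intakes.csv",
             doses = "doses.csv", isotopes = "isotopes.csv")
  out <- lapply(files, function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  })
  out[!vapply(out, is.null, logical(1))]
}
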