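#' Default pipeline configuration
#'
#' The full parameter set for [run_pipeline()]: cohort-generator settings
#' (see [cohort_config()]), Goldberg cut-off parameters per instrument,
#' DLW-engine constants and analysis options. Any element can be overridden
#' via `...` using the same nesting, or supplied from YAML with
#' [read_config()].
#'
#' @param seed master seed; every stochastic stage derives from it.
#' @param ... named overrides for `cohort`, `cutoffs`, `constants` or
#'   `analysis` sub-lists (partial lists are merged over the defaults).
#' @return Nested list of class `"pipeline_config"`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(),   # overrides passed to cohort_config()
    cutoffs = list(
      record = list(cv_tee = 8.4, cv_ei = 20.6, d = 4, z = 2),
      ffq = list(cv_tee = 8.4, cv_ei = 20.6, d = Inf, z = 2)
    ),
    constants = list(),  # overrides passed to dlw_constants()
    analysis = list(
      nutrients = c("protein", "fat", "sfa", "mufa", "pufa",
                    "carbohydrate", "sucrose", "fibre", "alcohol"),
      adjust_by_sex = TRUE,
      kappa_scheme = "linear",
      energy_bins = 3L,     # tertiles for energy ranking
      nutrient_bins = 4L,   # quartiles for nutrient ranking
      strict_qc = FALSE
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys follow [default_config()].
#' @return A `"pipeline_config"` list (defaults merged with the file).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  do.call(default_config,
          c(list(seed = if (!is.null(y$seed)) y$seed else 1L),
            y[setdiff(names(y), "seed")]))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full validation pipeline
#'
#' Executes every stage in order: cohort simulation, isotope-series
#' generation, the DLW engine, misreporting classification, energy
#' adjustment, and the agreement/ranking analyses; then assembles a
#' validation report. All randomness derives from `config$seed`, so a fixed
#' configuration reproduces the report bit-for-bit.
#'
#' @param config a [default_config()] list, or a path to a YAML file.
#' @param out_dir optional directory; when given, intermediate tables
#'   (`subjects.csv`, `intakes.csv`, `doses.csv`, `isotopes.csv`,
#'   `dlw_results.csv`, `misreporting.csv`, `adjusted_intakes.csv`,
#'   `agreement.csv`, `correlations.csv`, `crossclass.csv`) and the report
#'   (`report.json`, `report.txt`) are written there.
#' @param cohort_dir optional directory of previously written cohort tables;
#'   when given, the simulation stage is skipped and tables are read from
#'   disk instead (stage idempotence).
#' @return An object of class `"validation_report"`.
#' @examples
#' rep <- run_pipeline(default_config(seed = 1,
#'                                    cohort = list(n_subjects = 60,
#'                                                  n_dlw_subjects = 12)))
#' rep$accuracy
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         cohort_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  ccfg <- do.call(cohort_config,
                  c(list(seed = config$seed), config$cohort))
  cst <- do.call(dlw_constants, config$constants)
  an <- config$analysis

  # -- stage: simulate (or reload) ------------------------------------------
  if (is.null(cohort_dir)) {
    cohort <- generate_cohort(ccfg)
    iso <- generate_isotope_series(cohort$subjects, ccfg)
    subjects <- cohort$subjects
    intakes <- cohort$intakes
  } else {
    tabs <- read_cohort(cohort_dir)
    subjects <- tabs$subjects
    intakes <- tabs$intakes
    iso <- list(doses = tabs$doses, isotopes = tabs$isotopes)
  }

  # -- stage: dlw -----------------------------------------------------------
  dlw <- dlw_cohort(iso$isotopes, iso$doses, cst)
  if (isTRUE(an$strict_qc) && any(nzchar(dlw$qc_flags)))
    stop("QC failures under strict mode: ",
         paste(dlw$subject_id[nzchar(dlw$qc_flags)], collapse = ", "),
         call. = FALSE)

  # -- stage: misreporting --------------------------------------------------
  dlw_intakes <- intakes[intakes$subject_id %in% dlw$subject_id, ]
  mis <- do.call(rbind, lapply(c("record", "ffq"), function(instr) {
    sub <- dlw_intakes[dlw_intakes$instrument == instr, ]
    tee <- dlw$tee[match(sub$subject_id, dlw$subject_id)]
    lim <- do.call(goldberg_limits, config$cutoffs[[instr]])
    cls <- classify_reporter(sub$energy, tee, lim)
    data.frame(subject_id = sub$subject_id, instrument = instr,
               ei = sub$energy, tee = tee,
               ratio = cls$ratio, status = as.character(cls$status),
               accuracy_pct = reporting_accuracy(sub$energy, tee),
               stringsAsFactors = FALSE)
  }))
  limits <- lapply(config$cutoffs, function(p) do.call(goldberg_limits, p))

  # -- stage: adjust --------------------------------------------------------
  adjusted <- adjust_intakes(intakes, subjects, an$nutrients,
                             by_sex = an$adjust_by_sex, method = "residual")
  densities <- adjust_intakes(intakes, subjects, an$nutrients,
                              by_sex = FALSE, method = "density")

  # -- stage: agreement / ranking -------------------------------------------
  energy_vs_tee <- lapply(c(record = "record", ffq = "ffq"), function(instr) {
    m <- mis[mis$instrument == instr, ]
    ok <- is.finite(m$tee)
    ba <- bland_altman(m$ei[ok], m$tee[ok])
    cc <- cross_classify(quantile_bins(m$ei[ok], an$energy_bins),
                         quantile_bins(m$tee[ok], an$energy_bins),
                         k = an$energy_bins, scheme = an$kappa_scheme)
    list(bland_altman = ba,
         calibration = calibration_slope(m$ei[ok], m$tee[ok]),
         pearson = correlate(m$ei[ok], m$tee[ok], "adjusted_pearson"),
         cross_class = cc)
  })

  rec <- intakes[intakes$instrument == "record", ]
  ffq <- intakes[intakes$instrument == "ffq", ]
  ffq <- ffq[match(rec$subject_id, ffq$subject_id), ]
  method_vars <- c("energy", an$nutrients)
  between_methods <- lapply(stats::setNames(method_vars, method_vars),
                            function(v) {
    adj_pair <- if (v == "energy") NULL else {
      a <- adjusted[adjusted$nutrient == v, ]
      ar <- a[a$instrument == "record", ]
      af <- a[a$instrument == "ffq", ]
      af <- af[match(ar$subject_id, af$subject_id), ]
      list(record = ar$value, ffq = af$value,
           transformation = ar$transformation[1])
    }
    k <- if (v == "energy") an$energy_bins else an$nutrient_bins
    rank_r <- if (v == "energy") rec[[v]] else adj_pair$record
    rank_f <- if (v == "energy") ffq[[v]] else adj_pair$ffq
    list(wilcoxon = paired_compare(rec[[v]], ffq[[v]]),
         spearman_crude = correlate(rec[[v]], ffq[[v]], "crude_spearman"),
         pearson_adjusted = if (is.null(adj_pair)) NULL else
           correlate(adj_pair$record, adj_pair$ffq, "adjusted_pearson"),
         transformation = if (is.null(adj_pair)) "none"
                          else adj_pair$transformation,
         cross_class = cross_classify(quantile_bins(rank_r, k),
                                      quantile_bins(rank_f, k),
                                      k = k, scheme = an$kappa_scheme))
  })

  # -- stage: report --------------------------------------------------------
  tee_ok <- dlw$tee[is.finite(dlw$tee)]
  tee_ci <- mean(tee_ok) + c(-1, 1) * stats::qt(0.975, length(tee_ok) - 1) *
    stats::sd(tee_ok) / sqrt(length(tee_ok))
  status_tab <- lapply(split(mis, mis$instrument), function(m) {
    tb <- table(factor(m$status, levels = c("under", "plausible", "over")))
    list(counts = as.list(tb), percentages = as.list(100 * tb / sum(tb)))
  })
  accuracy <- lapply(split(mis, mis$instrument), function(m)
    reporting_accuracy(m$ei, m$tee, summarise = TRUE))
  ei_diff <- lapply(split(mis, mis$instrument), function(m)
    c(mean = mean(m$ei - m$tee), sd = stats::sd(m$ei - m$tee)))

  report <- structure(list(
    cohort_summary = list(
      n_subjects = nrow(subjects),
      n_dlw = nrow(dlw),
      n_by_sex = as.list(table(subjects$sex)),
      n_obese = sum(subjects$bmi > 30)),
    tee = list(mean = mean(tee_ok), ci_lower = tee_ci[1],
               ci_upper = tee_ci[2], sd = stats::sd(tee_ok),
               n = length(tee_ok)),
    ei_mean = lapply(split(mis, mis$instrument), function(m) mean(m$ei)),
    ei_minus_tee = ei_diff,
    accuracy = accuracy,
    limits = limits,
    reporter_status = status_tab,
    energy_vs_tee = energy_vs_tee,
    between_methods = between_methods,
    tables = list(subjects = subjects, intakes = intakes,
                  doses = iso$doses, isotopes = iso$isotopes,
                  dlw_results = dlw, misreporting = mis,
                  adjusted_intakes = adjusted, densities = densities),
    metadata = list(seed = config$seed,
                    config_hash = config_hash(config),
                    kappa_scheme = an$kappa_scheme,
                    adjust_by_sex = an$adjust_by_sex,
                    pool_convention = cst$pool_convention,
                    food_quotient = cst$food_quotient,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "validation_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tb <- report$tables
  for (nm in names(tb))
    utils::write.csv(tb[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)

  corr_rows <- do.call(rbind, lapply(names(report$between_methods),
                                     function(v) {
    bm <- report$between_methods[[v]]
    data.frame(variable = v,
               spearman_crude = bm$spearman_crude$estimate,
               spearman_p = bm$spearman_crude$p_value,
               pearson_adjusted = if (is.null(bm$pearson_adjusted)) NA
                                  else bm$pearson_adjusted$estimate,
               pearson_p = if (is.null(bm$pearson_adjusted)) NA
                           else bm$pearson_adjusted$p_value,
               transformation = bm$transformation,
               wilcoxon_p = bm$wilcoxon$p_value,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(corr_rows, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)

  cc_row <- function(label, cc)
    data.frame(comparison = label, k = nrow(cc$table),
               pct_same = cc$pct_same, pct_adjacent = cc$pct_adjacent,
               pct_opposite = cc$pct_opposite,
               kappa_weighted = cc$kappa_weighted,
               weight_scheme = cc$weight_scheme,
               stringsAsFactors = FALSE)
  cc_rows <- rbind(
    do.call(rbind, lapply(names(report$energy_vs_tee), function(i)
      cc_row(paste0("energy_", i, "_vs_tee"),
             report$energy_vs_tee[[i]]$cross_class))),
    do.call(rbind, lapply(names(report$between_methods), function(v)
      cc_row(paste0(v, "_record_vs_ffq"),
             report$between_methods[[v]]$cross_class))))
  utils::write.csv(cc_rows, file.path(out_dir, "crossclass.csv"),
                   row.names = FALSE)

  ba_row <- function(label, ba)
    data.frame(comparison = label, mean_difference = ba$mean_difference,
               sd_difference = ba$sd_difference, loa_lower = ba$loa_lower,
               loa_upper = ba$loa_upper, pct_outside = ba$pct_outside_loa,
               trend_slope = ba$trend_slope, trend_p = ba$trend_p,
               stringsAsFactors = FALSE)
  ba_rows <- do.call(rbind, lapply(names(report$energy_vs_tee), function(i)
    ba_row(paste0("energy_", i, "_vs_tee"),
           report$energy_vs_tee[[i]]$bland_altman)))
  utils::write.csv(ba_rows, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE)

  json <- report[setdiff(names(report), "tables")]
  json$energy_vs_tee <- lapply(json$energy_vs_tee, function(e) {
    e$bland_altman <- unclass(e$bland_altman)[
      c("mean_difference", "sd_difference", "loa_lower", "loa_upper",
        "pct_outside_loa", "trend_slope", "trend_p")]
    e$cross_class <- summarise_cc(e$cross_class)
    e
  })
  json$between_methods <- lapply(json$between_methods, function(e) {
    e$cross_class <- summarise_cc(e$cross_class)
    e
  })
  json$limits <- lapply(json$limits, unclass)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

summarise_cc <- function(cc)
  list(pct_same = cc$pct_same, pct_adjacent = cc$pct_adjacent,
       pct_opposite = cc$pct_opposite, kappa_weighted = cc$kappa_weighted,
       weight_scheme = cc$weight_scheme)

#' @export
print.validation_report <- function(x, ...) {
  cat("Dietary instrument validation against doubly labelled water\n")
  cat(sprintf("  cohort: %d subjects (%d with DLW); seed %d\n",
              x$cohort_summary$n_subjects, x$cohort_summary$n_dlw,
              x$metadata$seed))
  cat(sprintf("  TEE: mean %.1f MJ/d (95%% CI %.1f, %.1f)\n",
              x$tee$mean, x$tee$ci_lower, x$tee$ci_upper))
  for (instr in names(x$accuracy)) {
    acc <- x$accuracy[[instr]]
    st <- x$reporter_status[[instr]]
    lim <- x$limits[[instr]]
    ev <- x$energy_vs_tee[[instr]]
    cat(sprintf("  %s:\n", instr))
    cat(sprintf("    mean EI %.1f MJ/d; EI - TEE %.1f (sd %.1f) MJ/d\n",
                x$ei_mean[[instr]], x$ei_minus_tee[[instr]]["mean"],
                x$ei_minus_tee[[instr]]["sd"]))
    cat(sprintf("    reporting accuracy %.0f (sd %.0f) %%\n",
                acc["mean"], acc["sd"]))
    cat(sprintf("    cut-offs (%.2f, %.2f): %d under (%.1f%%), %d over (%.1f%%)\n",
                lim$lower_rounded, lim$upper_rounded,
                st$counts$under, st$percentages$under,
                st$counts$over, st$percentages$over))
    cat(sprintf("    calibration slope %.2f (95%% CI %.2f, %.2f); r = %.2f\n",
                ev$calibration$slope, ev$calibration$ci_lower,
                ev$calibration$ci_upper, ev$pearson$estimate))
    cat(sprintf("    tertile agreement: same %.1f%%, opposite %.1f%%, kappa_w %.2f\n",
                ev$cross_class$pct_same, ev$cross_class$pct_opposite,
                ev$cross_class$kappa_weighted))
  }
  en <- x$between_methods$energy
  cat(sprintf("  record vs ffq (energy): rho = %.2f, kappa_w = %.2f\n",
              en$spearman_crude$estimate, en$cross_class$kappa_weighted))
  invisible(x)
}

#' @export
summary.validation_report <- function(object, ...) {
  print(object)
  cat("\nBetween-method nutrient comparisons:\n")
  for (v in setdiff(names(object$between_methods), "energy")) {
    bm <- object$between_methods[[v]]
    cat(sprintf(paste0("  %-12s rho %.2f, r_adj %.2f (%s), ",
                       "kappa_w %.2f, Wilcoxon P %s\n"),
                v, bm$spearman_crude$estimate,
                bm$pearson_adjusted$estimate, bm$transformation,
                bm$cross_class$kappa_weighted,
                format.pval(bm$wilcoxon$p_value, digits = 2)))
  }
  invisible(object)
}
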