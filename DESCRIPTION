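Package: dietvalid
Title: Validation of Dietary Assessment Instruments Against Doubly Labelled Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective validation of self-reported dietary intake
    against total energy expenditure measured with the doubly labelled water
    (DLW) technique. Implements the multipoint DLW calculation (log-linear
    isotope elimination fits, dilution spaces, fractionation-corrected CO2
    production and energy expenditure with quality-control flags),
    Goldberg/Black confidence-limit classification of energy-intake
    misreporting, residual-model and energy-density adjustment of nutrient
    intakes, and instrument-agreement statistics (Bland-Altman limits of
    agreement, calibration slopes, Wilcoxon signed-rank comparisons,
    crude and energy-adjusted correlations, quantile cross-classification
    and Cohen's weighted kappa). A seeded synthetic-cohort generator with
    first-order isotope kinetics makes the full pipeline testable without
    access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
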