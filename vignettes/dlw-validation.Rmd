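---
title: "Validating dietary instruments against doubly labelled water: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating dietary instruments against doubly labelled water}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietvalid)
```

## The problem

Self-reported dietary intake is the backbone of nutrition epidemiology and
its weakest link: energy intake (EI) from food records and food-frequency
questionnaires (FFQs) is under-reported, selectively and non-randomly. In
weight-stable adults, total energy expenditure (TEE) equals true energy
intake, and TEE can be measured objectively in free-living people with
doubly labelled water (DLW): after an oral dose of water labelled with
deuterium and oxygen-18, the two isotopes wash out of body water at
different rates — ²H leaves as water only, ¹⁸O as both water and CO₂ — so
the difference between their elimination constants measures CO₂ production
and hence energy expenditure.

`dietvalid` implements the complete analysis such a validation study runs:
the DLW calculation itself, classification of implausible reporters,
energy adjustment of nutrients, and the agreement and ranking statistics
used to compare two instruments with each other and with the DLW yardstick.
A seeded synthetic-cohort generator stands in for raw study data, which are
rarely shareable.

## The DLW engine

### Elimination fits

For each isotope, `fit_elimination()` performs OLS of log excess enrichment
(ppm above the subject's own pre-dose background) on time — the multipoint
method, using every post-dose sample rather than a two-point protocol. The
elimination constant is $k = -\text{slope}$ and the back-extrapolated
zero-time intercept estimates the plateau enrichment. Residuals are kept on
the log scale; externally studentized residuals support the outlier check.

### Dilution spaces

`compute_dilution_space()` converts the dose record into moles of excess
tracer atoms — for a dose of mass $m$ containing mass fraction $f$ of
labelled water at atom-fraction purity $p$, the ¹⁸O tracer is
$m f p / M$ mol and the ²H tracer $2 m f p / M$ mol ($M$ the molar mass of
the labelled water; two hydrogen positions per molecule) — and divides by
the intercept atom-fraction excess. The ratio $N_H/N_O$ of the two dilution
spaces is a technique quality measure: physiologically it sits near 1.03,
and results outside the window $[1.00, 1.07]$ are flagged.

### CO₂ production and energy

`dlw_tee()` uses the two-pool multipoint form

$$ r\mathrm{CO_2} = \frac{N}{2.078}\,(1.007\,k_O - 1.041\,k_H)
   \;-\; 0.0246\, r_{Gf}, \qquad
   r_{Gf} = 1.05\, N\,(1.007\,k_O - 1.041\,k_H), $$

where $N$ is the body-water pool — by default the ¹⁸O dilution space
scaled by 1.01 (the ²H space scaled by 1.04, or the mean of the two, are
available through `dlw_constants(pool_convention=)`). The second term is
the fractionation correction for water lost by evaporation. Energy follows
the Weir form $EE = V\mathrm{CO_2}\,(1.106 + 3.941/FQ)$ with the molar
volume 22.414 L/mol and 4.184 kJ/kcal. All constants are collected in
`dlw_constants()` rather than hard-coded: laboratories differ in the exact
coefficient set, and exposing them keeps any recalculation auditable.

The **food quotient** (FQ) converts CO₂ to energy in place of an unmeasured
respiratory quotient. The default 0.85 is the usual mixed-diet value; on
the Weir factor, moving FQ by ±0.02 moves TEE by roughly ∓2%, so per-diet
FQs should be supplied when food records are trusted for composition.

### Quality control

`qc_check()` applies three flags-only rules: the dilution-space ratio
window above; study-period weight change beyond ±1 kg (weight stability is
the premise for equating TEE with intake); and any elimination-curve point
with $|$externally studentized residual$| > 3$. With only four post-dose
samples the studentized statistic has one denominator degree of freedom, so
this flag is sensitive by design — it marks curves a human should look at,
and it never invalidates a result by itself. A non-positive rate
difference $1.007\,k_O - 1.041\,k_H$ does invalidate TEE (`NA`, flagged
`invalid_turnover`).

## Misreporting classification

`goldberg_limits()` computes the 95% confidence limits of EI:TEE around its
expected value 1,

$$ 1 \mp z\,\frac{\sqrt{CV_{EI}^2/d + CV_{TEE}^2}}{100}, $$

with within-subject CVs in percent, $d$ recording days and $z = 2$. The
defaults — $CV_{TEE} = 8.4$% over a two-week protocol and $CV_{EI} = 20.6$%
for record-based EI — give cut-offs (0.73, 1.27) at $d = 4$; an FFQ
reflects habitual intake, so $d \to \infty$ removes the EI term and gives
(0.83, 1.17). Classification (`classify_reporter()`) uses strict
inequalities against the 2-decimal rounded limits by default, reproducing
how printed thresholds are applied in practice; an unrounded mode is
available (`use_rounded = FALSE`). Boundary ties are plausible. These are
the single-subject Goldberg limits — group-level variants with
between-subject CV terms and PAL stratification are out of scope.

## Energy adjustment

`residual_adjust()` implements the residual model: OLS of nutrient on
energy, adjusted value = residual + fitted value at the cohort mean energy.
The adjusted series is exactly uncorrelated with energy (to numerical
precision) and the adjustment is idempotent. `energy_density()` provides
the unit/MJ alternative used for Bland–Altman comparisons of composition.

Intake variables are right-skewed, so each variable is transformed before
correlation and adjustment. `choose_transformation()` picks log or square
root per variable, whichever leaves the smaller absolute sample skewness
(ties to log); the choice is recorded in the output so it is reproducible
and auditable. Zeros (alcohol, typically) receive half the smallest
positive observed value before the log — a conventional, data-scaled
offset. `adjust_intakes()` applies transform-then-adjust (the standard
residual-model order), regressing on log energy, within sex strata by
default because intake distributions differ by sex; a pooled mode exists.

## Agreement and ranking

- `bland_altman()`: mean difference, sample-SD limits at ±1.96 SD, the
  share of pairs outside the limits, and proportional bias as the OLS slope
  of difference on pairwise mean with its two-sided p ("P for trend").
- `calibration_slope()`: OLS of measured TEE on reported EI; the 95% CI
  uses the slope's standard error and the t-quantile at $n-2$ df. A slope
  of 1 would mean reported intake tracks expenditure one-to-one;
  attenuated slopes are the norm.
- `paired_compare()`: Wilcoxon signed-rank via `stats::wilcox.test`
  (exact for ≤ 25 non-zero differences without ties; normal approximation
  with tie/continuity correction otherwise). Zero differences are dropped
  before ranking and counted; an all-zero comparison is flagged degenerate
  rather than tested.
- `correlate()`: Spearman (midranks) for crude intakes, Pearson for
  transformed, energy-adjusted intakes.
- `quantile_bins()` + `cross_classify()` + `weighted_kappa()`: tertiles
  for energy, quartiles for nutrients, split at type-7 sample quantiles
  with right-closed intervals so boundary-tied values fall in the lower bin
  (a deterministic, stated rule; heavy ties collapse bins with a warning).
  Cross-classification reports same / adjacent / opposite shares —
  "opposite" is strictly the two corner cells — and Cohen's weighted
  $\kappa_w = 1 - \sum w_{ij} p_{ij} / \sum w_{ij} \hat p_{ij}$ with linear
  disagreement weights $w_{ij} = |i-j|/(k-1)$ by default (quadratic
  available); linear is the common choice for ordinal diet quantiles, and
  the scheme is echoed in every output.

## The synthetic cohort

`generate_cohort()` emulates the structure the analysis assumes, not any
particular dataset:

| parameter | default | rationale |
|---|---|---|
| cohort / DLW subgroup | 200 / 40 | typical validation-substudy sizes |
| true TEE | N(10.8, 2.7) MJ/d, truncated at 0 | mean from the middle-aged range; SD back-calculated from a 95% CI of (9.9, 11.6) for a mean of 40 |
| reporting accuracy | record N(0.80, 0.23), FFQ N(0.82, 0.33), truncated at 0 | only two moments are ever reported for accuracy distributions; a truncated normal is the simplest distribution matching them |
| within-subject CV of record EI | 20.6% | day-to-day intake variation |
| within-subject CV of FFQ EI | 0% | an FFQ averages months of intake ("infinite days"); its accuracy SD carries all spread; exposed as `cv_within_ffq` |
| energy shares protein/fat/carb/alcohol | 0.17/0.34/0.45/0.04 | a realistic middle-aged Western diet |
| energy factors | 17/37/17/29 kJ/g | standard food-composition convention |
| total body water | 50% (women), 58% (men) of weight | standard adult values |
| sampling days | 1, 3, 12, 14 | the two-week urine protocol |
| dose | 1 g DLW/kg; 0.6 (men) / 0.5 (women) g/kg above BMI 30 | body water per kg falls with BMI |
| enrichment noise | 1% multiplicative | isotope-ratio MS precision |
| $k_O/k_H$ ratio | 1.25 | with the TEE inversion this pins $k_H \approx 0.09$/d, $k_O \approx 0.11$/d, typical adult turnover |
| weight change | N(0, 0.3) kg clipped to ±1 | weight-stable by design |

Reported energy is `true_tee × accuracy × noise`; macronutrient grams are
back-calculated from reported energy via per-subject jittered,
renormalised shares, so energy and macronutrients are exactly consistent
by construction. `generate_isotope_series()` inverts the engine's own
forward model: pool sizes come from body weight, intercepts from the dose,
and $k_O, k_H$ from the target TEE, so a noise-free cohort round-trips
through `dlw_tee()` exactly — a closure property the tests exploit.

What the generator does **not** emulate: correlated reporting errors
across instruments within a subject (beyond the shared true TEE),
BMI- or SES-dependent under-reporting, seasonal variation, item-level
records, or isotope background drift. Passing tests therefore demonstrate
that the statistical machinery is correct and calibrated — not that any
particular field result will replicate, since those depend on error
structures the simulation deliberately leaves out.

## Numerical choices

- All elimination fits run on the log scale; non-positive enrichments are
  excluded with a warning, and fewer than two usable samples is an error.
- Numerically perfect fits (noise-free simulations) would make studentized
  residuals 0/0; residual SDs below 1e-10 set them to zero instead.
- Cohort SDs (reporting accuracy, Bland–Altman) use the sample $n-1$
  denominator, as in descriptive tables.
- Degenerate inputs fail loudly: zero energy variance in the residual
  model, zero variance in correlations, empty kappa tables, `d ≤ 0` in the
  Goldberg formula are all errors; all-zero Wilcoxon differences and
  collapsed quantile bins are flagged/warned, not silently dropped.
- Problem sizes in the checks: 40 noise-free subjects for the round-trip,
  1000 replicates for noise bias and CI coverage, 10 000 pairs for
  limits-of-agreement coverage, 100 000 draws for the under-reporter
  fraction against its closed form. These give Monte-Carlo error well
  inside each stated tolerance.

## Reproducibility

Everything stochastic descends from one integer seed: `generate_cohort()`
seeds at `seed`, `generate_isotope_series()` at `seed + 1`, and
`run_pipeline()` records the seed and an MD5 hash of the full configuration
in its report metadata, so a report is reproducible bit-for-bit and any
parameter change is visible in the hash. Intermediate tables are plain CSV;
re-running the pipeline on written tables (`cohort_dir=`) reproduces the
report.

## Known limitations

- The Goldberg limits implemented are the single-subject form; cohort-level
  screening with between-subject variance terms is not included.
- The DLW constants are one published coefficient set; laboratories using
  different fractionation assumptions should override `dlw_constants()`.
- Attenuation factors and validity coefficients (method-of-triads) are out
  of scope — they need replicate reference measurements and larger DLW
  samples than validation substudies usually have.
- With four-point elimination curves the residual-outlier flag has low
  specificity (one denominator df); treat it as a prompt for inspection.
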