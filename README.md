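# dietvalid

Objective validation of self-reported dietary intake against total energy
expenditure (TEE) measured with the doubly labelled water (DLW) technique.

Self-reported energy intake (EI) from food records and food-frequency
questionnaires (FFQs) is systematically under-reported. In weight-stable
adults TEE equals true energy intake, so a DLW measurement gives an
objective yardstick: the ratio EI:TEE should be 1 under perfect reporting.
`dietvalid` implements the full statistical pipeline such a validation study
needs, for nutrition epidemiologists evaluating dietary assessment
instruments:

- **DLW engine** — the multipoint method. For each isotope, ordinary least
  squares of log excess enrichment on time gives the elimination constant
  *k* = −slope and the back-extrapolated intercept; the dilution space is
  *N* = (mol tracer dosed) / (intercept atom-fraction excess). CO₂
  production uses the two-pool form

  *r*CO₂ = (N/2.078)(1.007 k_O − 1.041 k_H) − 0.0246 · 1.05 · N (1.007 k_O − 1.041 k_H)

  and energy expenditure follows the Weir equation
  EE = VCO₂ (1.106 + 3.941/FQ) with a configurable food quotient.
  Quality control flags dilution-space ratios N_H/N_O outside [1.00, 1.07],
  body-weight changes beyond ±1 kg, and diverging elimination-curve
  residuals.
- **Misreporting classification** — Goldberg/Black 95% confidence limits
  around EI:TEE = 1: limits = 1 ∓ z √(CV²_EI/d + CV²_TEE)/100. With
  CV_TEE = 8.4%, CV_EI = 20.6%, z = 2 this gives cut-offs (0.73, 1.27) for a
  4-day record and (0.83, 1.17) for an FFQ (d = ∞), plus reporting accuracy
  100·EI/TEE.
- **Energy adjustment** — the residual model (residual + fitted value at
  mean energy, within sex strata) and energy densities (unit/MJ), with a
  data-driven log-vs-square-root transformation rule.
- **Agreement and ranking** — Bland–Altman limits of agreement with a
  proportional-bias trend test, calibration slopes (OLS of TEE on EI with
  95% CI), Wilcoxon signed-rank comparisons, Spearman (crude) and Pearson
  (energy-adjusted) correlations, tertile/quartile cross-classification and
  Cohen's weighted κ.
- **Synthetic cohort generator** — seeded, with first-order isotope
  kinetics inverted from the engine's own equations, so the whole pipeline
  is testable end-to-end without access to raw study data.

## Worked example

```r
library(dietvalid)

goldberg_limits(cv_tee = 8.4, cv_ei = 20.6, d = 4, z = 2)
#> Goldberg cut-offs for EI:TEE (CV_TEE 8.4%, CV_EI 20.6%, d = 4, z = 2):
#>   under-reporting  < 0.73   over-reporting > 1.27
#>   (unrounded 0.734181, 1.265819)

rep <- run_pipeline(default_config(seed = 1))
print(rep)
#> Dietary instrument validation against doubly labelled water
#>   cohort: 200 subjects (40 with DLW); seed 1
#>   TEE: mean 11.0 MJ/d (95% CI 10.1, 11.8)
#>   ffq:
#>     mean EI 8.6 MJ/d; EI - TEE -2.4 (sd 3.6) MJ/d
#>     reporting accuracy 77 (sd 32) %
#>     cut-offs (0.83, 1.17): 25 under (62.5%), 5 over (12.5%)
#>     calibration slope 0.36 (95% CI 0.20, 0.52); r = 0.60
#>     tertile agreement: same 52.5%, opposite 2.5%, kappa_w 0.44
#>   record:
#>     mean EI 8.7 MJ/d; EI - TEE -2.3 (sd 3.3) MJ/d
#>     reporting accuracy 78 (sd 29) %
#>     cut-offs (0.73, 1.27): 19 under (47.5%), 3 over (7.5%)
#>     calibration slope 0.41 (95% CI 0.26, 0.56); r = 0.67
#>     tertile agreement: same 52.5%, opposite 7.5%, kappa_w 0.38
#>   record vs ffq (energy): rho = 0.32, kappa_w = 0.19
```

Reading the output: the simulated cohort expends on average 11.0 MJ/d while
reporting 8.6–8.7 MJ/d, i.e. both instruments under-report by roughly 2.3–2.4
MJ/d (a reporting accuracy near 80%); nearly half of the DLW subgroup falls
below the record's under-reporting cut-off of 0.73; calibration slopes well
below 1 and moderate tertile agreement show that neither instrument ranks
individuals sharply. Each such quantity is also available programmatically
(`rep$accuracy`, `rep$energy_vs_tee$record$calibration`, ...) and as CSV/JSON
files via `run_pipeline(..., out_dir = "out")`.

Single-subject DLW fits are first-class model objects:

```r
cfg <- cohort_config(n_subjects = 2, n_dlw_subjects = 1, seed = 3,
                     enrichment_noise_sd = 0.01)
coh <- generate_cohort(cfg)
iso <- generate_isotope_series(coh$subjects, cfg)
fit <- dlw_tee(iso$isotopes, iso$doses)
coef(fit)        # k_h, k_o, dilution spaces, rCO2, TEE
summary(fit)     # per-sample residual diagnostics
plot(fit)        # semi-log elimination curves
```

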