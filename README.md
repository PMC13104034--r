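# hepaPFAS

Analysis pipeline for targeted per- and polyfluoroalkyl substance (PFAS)
measurements in banked human liver tissue — for exposure scientists and
analytical chemists running multi-decade organ-level biomonitoring
studies.

Serum PFAS surveys are plentiful; organ-level data are not, and the
liver is where long-chain PFAS preferentially accumulate. hepaPFAS
covers the full chain from integrated instrument peak areas to
population-level inference:

- **Isotope-dilution quantification** with matrix-matched calibration
  and the QA/QC rules of performance-based targeted LC-HRMS methods:
  per-batch method detection limits (mean blank + 3·SD, IDL fallback),
  blank-correction gating at the MDL, retention-time windows (0.1 min,
  or 0.4 min with CCV shift correction for surrogate internal
  standards), ion-abundance-ratio confirmation (CCV-normalized, offset
  by one, accepted on [−1, 1]), internal-standard recovery limits, and
  record/sample exclusion logic.
- **Left-censored data handling**: explicit nondetect flags, MDL/2
  substitution, detection frequencies, summed PFAS, class composition
  by year, and period summaries with fold ranges.
- **Temporal trends**: weighted least squares of
  `log10(C) = β0 + β1·year` with weights `1/n_year` (inverse of each
  collection year's sample size), geometric means
  `GM(t) = 10^(β0 + β1 t)`, and percent reductions
  `100·(1 − 10^(β1·Δt))`.
- **Covariate models**: OLS of log10 concentration on sampling year,
  age, sex, and liver-health status (NAFLD) for every analyte detected
  in ≥ 30 donors plus the summed PFAS, with the percent-change
  transform `(10^β − 1)·100` (per decade for continuous predictors),
  variance inflation factors, and three residual-normality tests
  (Shapiro–Wilk, D'Agostino–Pearson K², Kolmogorov–Smirnov).
- **Extractable organofluorine (EOF) mass balance**: fluorine-equivalent
  conversion via each analyte's fluorine mass fraction and the
  fraction-of-EOF-explained computation.
- **A synthetic liver-cohort generator** reproducing the statistical
  structure such a study assumes (truncated-normal ages, year-correlated
  NAFLD prevalence with a configurable R², unequal per-year sampling,
  metadata gaps, and a full instrument model down to peak areas, blanks,
  CCVs and positive controls), so the whole pipeline is testable without
  restricted human data.

## Worked example

A complete synthetic run at the default study conditions (211 donors,
collection years 2000–2024):

```r
library(hepaPFAS)

cfg <- pipeline_config(seed = 17, sim = sim_params(n_donors = 211, seed = 17))
res <- run_pipeline(cfg)           # add out_dir = "run1" to write all CSVs

res$trend
#> Weighted log-linear trend (n = 168, 25 years)
#>   slope: -0.0202 log10/yr (-37.3% per decade), SE 0.0027, p = 2.88e-12
#>   weighted R2 = 0.255

percent_reduction(res$trend, 2000, 2024)
#> [1] 67.3

res$mlr[["sum"]]
#> Covariate model for sum (n = 191, R2 = 0.296, F-test p = 2e-13)
#>      predictor     beta      se  p_value percent_change significant
#> 1         year -0.01777 0.00302 1.91e-08         -33.58        TRUE
#> 2          age  0.00284 0.00125 2.48e-02           6.75        TRUE
#> 3   sex_female  0.00887 0.03436 7.96e-01           2.06       FALSE
#> 4 health_nafld -0.03033 0.04538 5.05e-01          -6.74       FALSE

median(res$mass_balance$fraction_explained)
#> [1] 7.6
```

Reading the output: the summed hepatic PFAS concentration declines by
37% per decade in the inverse-sample-size-weighted trend (67% over the
24-year window); in the covariate model the sampling-year effect
(−34%/decade) dominates, age adds ~7% per decade of age, and the
synthetic NAFLD effect (−7% here) is a noisy realization of the
configured −23% — single-seed covariate estimates carry substantial
sampling error at this cohort size. The targeted panel explains ~8% of
the extractable organofluorine, i.e. a ~13-fold gap between total
organofluorine and the sum of the measured PFAS in fluorine
equivalents.

With `out_dir` set, every stage writes an RFC-4180 CSV (`donors.csv`,
`batch.csv`, `concentrations.csv`, `qc_report.csv`, `cohort.csv`,
`detection_frequency.csv`, `composition_by_year.csv`,
`period_summary.csv`, `trend_fits.csv`, `mlr_results.csv`,
`mlr_diagnostics.csv`, `mass_balance.csv`) plus a `manifest.json` with
config and output hashes; identical config + seed reproduce identical
bytes. Real data enter through the same CSV schemas via the `inputs`
argument of `run_pipeline()`, validated by `validate_inputs()`.

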