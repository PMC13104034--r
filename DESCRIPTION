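Package: hepaPFAS
Title: Hepatic PFAS Biomonitoring: Isotope-Dilution Quantification,
    Censored-Data Trends, and Organofluorine Mass Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted per- and polyfluoroalkyl
    substance (PFAS) measurements in banked human liver tissue.
    Implements isotope-dilution quantification against matrix-matched
    calibration with the associated batch QA/QC rules (method detection
    limits from procedural blanks, blank-correction gating, retention-time
    windows, ion-abundance-ratio confirmation, internal-standard recovery,
    and exclusion logic), left-censored data handling by MDL/2
    substitution, inverse-sample-size-weighted log-linear temporal trend
    models with geometric-mean and percent-reduction summaries,
    multivariate covariate models (sampling year, age, sex, liver health)
    with a percent-change coefficient transform and collinearity and
    residual-normality diagnostics, and extractable-organofluorine (EOF)
    mass balance via fluorine-equivalent conversion. A synthetic
    liver-cohort generator emulates the donor demographics and instrument
    data structure end to end so every stage is testable without
    restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
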