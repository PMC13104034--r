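# End-to-end pipeline driver: synthetic generation (or user-supplied CSV
# inputs) -> isotope-dilution quantification with QA/QC -> cohort assembly
# -> trends, covariate models and EOF mass balance, with every stage's
# table written as RFC-4180 CSV plus a run manifest. The pipeline is a
# pure function of (inputs, config, seed).

#' Pipeline run configuration
#'
#' Bundles thresholds and modes for a full run. All thresholds default to
#' the method's QA/QC conventions: retention-time windows 0.1 / 0.4 min,
#' ion-abundance-ratio bounds of +/- 1, EIS recovery 20--150%,
#' whole-sample exclusion above 75% failed/non-detected analytes,
#' detection threshold of 30 for covariate modeling, alpha = 0.05.
#'
#' @param seed Integer seed for the synthetic stage.
#' @param sim [sim_params()] for the synthetic stage (its seed is
#'   overridden by `seed`).
#' @param min_detects,alpha,recovery_limits,exclusion_fraction QA/QC and
#'   modeling thresholds.
#' @param trend_mode ∑PFAS values entering the trend fit:
#'   `"detected_only"` or `"substituted"`.
#' @param periods Year bins for [period_summary()].
#' @param eof_censored_mode Censored-analyte handling in the mass balance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_params(seed = seed),
                            min_detects = 30,
                            alpha = 0.05,
                            recovery_limits = c(0.2, 1.5),
                            exclusion_fraction = 0.75,
                            trend_mode = c("detected_only", "substituted"),
                            periods = list(
                              "2000-2005" = c(2000, 2005),
                              "2006-2010" = c(2006, 2010),
                              "2020-2024" = c(2020, 2024)
                            ),
                            eof_censored_mode = c("zero", "half_mdl")) {
  trend_mode <- match.arg(trend_mode)
  eof_censored_mode <- match.arg(eof_censored_mode)
  stopifnot(
    min_detects >= 0, alpha > 0, alpha < 1,
    length(recovery_limits) == 2, recovery_limits[1] < recovery_limits[2],
    exclusion_fraction > 0, exclusion_fraction <= 1
  )
  sim$seed <- as.integer(seed)
  structure(
    list(
      seed = as.integer(seed), sim = sim, min_detects = min_detects,
      alpha = alpha, recovery_limits = recovery_limits,
      exclusion_fraction = exclusion_fraction, trend_mode = trend_mode,
      periods = periods, eof_censored_mode = eof_censored_mode
    ),
    class = "pipeline_config"
  )
}

#' Validate pipeline input tables
#'
#' Per-file, per-column presence / type / range checks for the CSV schemas
#' the pipeline reads. Errors (schema violations) and warnings (range
#' oddities such as collection years outside 2000--2024) are
#' distinguished; validation itself never throws.
#'
#' @param paths Named list/vector of file paths; recognised names are
#'   `donors`, `batch`, `panel`, `eof`.
#' @return Tibble with `file`, `severity` (`"error"`/`"warning"`),
#'   `message`. Zero rows means fully valid.
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(file, severity, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      file = file, severity = severity, message = message
    )
  }
  read_or_note <- function(name) {
    path <- paths[[name]]
    if (is.null(path) || !file.exists(path)) {
      note(name, "error", sprintf("missing input file: %s", path %||% name))
      return(NULL)
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  need_cols <- function(df, name, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      note(name, "error", sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
      FALSE
    } else {
      TRUE
    }
  }
  if ("donors" %in% names(paths)) {
    d <- read_or_note("donors")
    if (!is.null(d) && need_cols(d, "donors", c("donor_id", "age", "sex", "health"))) {
      if (any(!is.na(d$age) & (d$age < 18 | d$age > 85))) {
        note("donors", "warning", "age outside 18-85")
      }
      yr <- d$year_exact %||% NA_real_
      if (any(!is.na(yr) & (yr < 2000 | yr > 2024))) {
        note("donors", "warning", "collection year outside 2000-2024")
      }
      bad_sex <- setdiff(stats::na.omit(unique(d$sex)), c("male", "female"))
      if (length(bad_sex)) note("donors", "error", "sex must be male/female")
    }
  }
  if ("batch" %in% names(paths)) {
    b <- read_or_note("batch")
    cols <- c(
      "sample_id", "analyte", "role", "area_quant", "area_conf",
      "area_eis", "rt_analyte", "rt_eis", "sample_mass", "eis_spike", "batch_id"
    )
    if (!is.null(b) && need_cols(b, "batch", cols)) {
      if (any(b$area_quant < 0 | b$area_conf < 0 | b$area_eis < 0, na.rm = TRUE)) {
        note("batch", "error", "negative peak area")
      }
      spec <- b[b$role == "specimen", ]
      if (any(!is.na(spec$sample_mass) & spec$sample_mass <= 0)) {
        note("batch", "error", "non-positive sample mass for specimen rows")
      }
      if (any(b$eis_spike <= 0, na.rm = TRUE)) {
        note("batch", "error", "non-positive EIS spike")
      }
    }
  }
  if ("panel" %in% names(paths)) {
    p <- read_or_note("panel")
    if (!is.null(p)) {
      ok <- tryCatch(
        {
          pfas_panel(p)
          TRUE
        },
        error = function(e) {
          note("panel", "error", conditionMessage(e))
          FALSE
        }
      )
      invisible(ok)
    }
  }
  if ("eof" %in% names(paths)) {
    e <- read_or_note("eof")
    cols <- c("sample_id", "fluoride_reading", "batch_id", "dilution_factor", "role")
    if (!is.null(e) && need_cols(e, "eof", cols)) {
      if (any(e$fluoride_reading < 0, na.rm = TRUE)) {
        note("eof", "error", "negative fluoride reading")
      }
      if (any(e$dilution_factor < 1, na.rm = TRUE)) {
        note("eof", "error", "dilution factor < 1")
      }
    }
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(file = character(), severity = character(), message = character())
  }
}

#' Run the full pipeline
#'
#' Generates the synthetic inputs (or reads user CSVs when `inputs` names
#' existing `donors`/`batch`/`panel`/`eof` files), quantifies with QA/QC,
#' assembles the cohort, fits the weighted ∑PFAS and per-analyte trends,
#' fits the covariate models, runs the EOF mass balance, and writes every
#' stage's output table to `out_dir` together with a JSON manifest of the
#' configuration and output hashes. Deterministic given config + seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param inputs Optional named list of input CSV paths; when `NULL`
#'   (default) the synthetic generator supplies all inputs.
#' @return Invisibly, a list with all intermediate objects: `cohort_meta`,
#'   `batch`, `quant`, `cohort`, `sums`, `trend`, `analyte_trends`,
#'   `mlr`, `mass_balance`, `detection`, `composition`, `periods`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  panel <- sim$panel

  if (is.null(inputs)) {
    donors <- generate_cohort(sim)
    true_conc <- generate_true_concentrations(donors, sim)
    batch <- generate_batches(true_conc, sim)
    calibration <- generate_calibration(sim)
    eof_meas <- generate_eof(true_conc, sim)
  } else {
    report <- validate_inputs(inputs)
    if (any(report$severity == "error")) {
      rlang::abort(
        paste0(
          "input validation failed:\n",
          paste(sprintf(
            "  [%s] %s", report$file[report$severity == "error"],
            report$message[report$severity == "error"]
          ), collapse = "\n")
        ),
        class = "hepapfas_schema_error"
      )
    }
    donors <- readr::read_csv(inputs$donors, show_col_types = FALSE, progress = FALSE)
    batch <- readr::read_csv(inputs$batch, show_col_types = FALSE, progress = FALSE)
    if (!is.null(inputs$panel)) panel <- read_panel(inputs$panel)
    calibration <- readr::read_csv(inputs$calibration,
      show_col_types = FALSE, progress = FALSE
    )
    eof_meas <- if (!is.null(inputs$eof)) {
      readr::read_csv(inputs$eof, show_col_types = FALSE, progress = FALSE)
    } else {
      NULL
    }
  }

  quant <- quantify_batch(batch, panel, calibration,
    recovery_limits = config$recovery_limits,
    sample_fail_fraction_threshold = config$exclusion_fraction
  )
  cohort <- build_cohort(quant$concentrations, donors)
  detection <- detection_frequency(cohort)
  sums <- sum_pfas(cohort, mode = config$trend_mode)
  trend_in <- sums[!is.na(sums$year) & sums$year_is_exact & sums$sum_pfas > 0, ]
  n_dropped <- sum(sums$sum_pfas <= 0, na.rm = TRUE)
  if (n_dropped > 0) {
    rlang::warn(sprintf(
      "%d donor(s) with all-ND sums dropped from the log-scale trend", n_dropped
    ))
  }
  trend <- fit_weighted_trend(trend_in$sum_pfas, trend_in$year)
  analyte_trends <- per_analyte_trends(
    dplyr::filter(cohort, .data$year_is_exact %in% TRUE),
    alpha = config$alpha
  )
  mlr <- fit_all_mlr(cohort, min_detects = config$min_detects)
  composition <- class_composition(cohort, panel)
  periods <- period_summary(sums, config$periods)
  mb <- if (!is.null(eof_meas)) {
    run_mass_balance(eof_meas, quant$concentrations, panel,
      censored_mode = config$eof_censored_mode
    )
  } else {
    NULL
  }

  result <- list(
    cohort_meta = donors, batch = batch, quant = quant, cohort = cohort,
    sums = sums, trend = trend, analyte_trends = analyte_trends, mlr = mlr,
    mass_balance = mb, detection = detection, composition = composition,
    periods = periods
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      readr::write_csv(df, file.path(out_dir, name))
      name
    }
    files <- c(
      wr(donors, "donors.csv"),
      wr(batch, "batch.csv"),
      wr(tibble::as_tibble(panel), "panel.csv"),
      wr(quant$concentrations, "concentrations.csv"),
      wr(quant$qc, "qc_report.csv"),
      wr(tibble::as_tibble(cohort), "cohort.csv"),
      wr(detection, "detection_frequency.csv"),
      wr(composition, "composition_by_year.csv"),
      wr(periods, "period_summary.csv"),
      wr(trend_fits_table(trend, analyte_trends), "trend_fits.csv"),
      wr(mlr_results_table(mlr), "mlr_results.csv"),
      wr(mlr_diagnostics_table(mlr), "mlr_diagnostics.csv")
    )
    if (!is.null(mb)) files <- c(files, wr(mb, "mass_balance.csv"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("hepaPFAS")),
      seed = config$seed,
      config_hash = rlang::hash(config),
      outputs = as.list(tools::md5sum(file.path(out_dir, files)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
    result$manifest <- manifest
  }
  invisible(result)
}

# Flat CSV twin of the sum + per-analyte trend fits.
trend_fits_table <- function(trend, analyte_trends) {
  sum_row <- tibble::tibble(
    analyte = "sum", beta0 = trend$beta0, beta1 = trend$beta1,
    se1 = trend$se1, p_value = trend$p_value, r2 = trend$r2,
    n_obs = trend$n_obs,
    label = if (is.na(trend$p_value) || trend$p_value >= 0.05) "no-change"
    else if (trend$beta1 < 0) "decline" else "increase"
  )
  tb <- dplyr::bind_rows(sum_row, analyte_trends)
  tb$gm_2000 <- 10^(tb$beta0 + tb$beta1 * 2000)
  tb$gm_2024 <- 10^(tb$beta0 + tb$beta1 * 2024)
  tb$percent_reduction_2000_2024 <- 100 * (1 - 10^(tb$beta1 * 24))
  tb
}

# One row per analyte x predictor.
mlr_results_table <- function(fits) {
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(analyte = f$analyte, f$coefficients)
  }))
}

mlr_diagnostics_table <- function(fits) {
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(
      analyte = f$analyte, n_obs = f$n_obs, r2 = f$r2,
      f_p_value = f$f_p_value,
      vif_year = f$vif[["year"]], vif_age = f$vif[["age"]],
      vif_sex = f$vif[["sex_female"]], vif_health = f$vif[["health_nafld"]],
      shapiro_wilk_p = f$normality[["shapiro_wilk"]],
      dagostino_pearson_p = f$normality[["dagostino_pearson"]],
      kolmogorov_smirnov_p = f$normality[["kolmogorov_smirnov"]]
    )
  }))
}
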