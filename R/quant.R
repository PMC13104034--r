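# Isotope-dilution quantification and batch QA/QC. Everything operates in
# ratio space (native/EIS), which makes quantification invariant to any
# proportional loss applied to both channels (the point of isotope
# dilution): halving both the analyte and the internal-standard areas
# leaves the result unchanged.

#' Fit a matrix-matched calibration curve
#'
#' Ordinary least squares of area ratio (native/EIS) on amount ratio
#' (native/EIS). At least five levels are required; a non-positive fitted
#' slope is refused, and a non-monotone mean response is flagged with a
#' warning.
#'
#' @param levels Data frame with columns `amount_ratio` and `area_ratio`
#'   (>= 5 rows), optionally `idl`.
#' @param analyte Analyte name to record on the curve.
#' @param idl Instrumental detection limit (ng/g), the concentration
#'   producing signal-to-noise 10; used as the MDL fallback when blanks
#'   show no analyte signal. Taken from `levels$idl` when present.
#' @param weighting `"none"` (default; ratio-space isotope dilution
#'   largely removes heteroscedasticity) or `"1/x"`.
#' @return A `calibration_curve` list: `analyte`, `slope`, `intercept`,
#'   `idl`, `levels`, `residuals`, `monotone`.
#' @export
fit_calibration <- function(levels, analyte = "analyte", idl = NA_real_,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("amount_ratio", "area_ratio") %in% names(levels)))
  if (nrow(levels) < 5) {
    rlang::abort("calibration requires at least 5 levels",
      class = "hepapfas_calibration_error"
    )
  }
  if ("idl" %in% names(levels) && is.na(idl)) idl <- levels$idl[1]
  w <- if (weighting == "1/x") 1 / pmax(levels$amount_ratio, 1e-12) else NULL
  fit <- stats::lm(area_ratio ~ amount_ratio, data = levels, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    rlang::abort("calibration slope must be positive",
      class = "hepapfas_calibration_error"
    )
  }
  ord <- order(levels$amount_ratio)
  mono <- !is.unsorted(tapply(
    levels$area_ratio[ord], levels$amount_ratio[ord], mean
  ))
  if (!mono) {
    rlang::warn(sprintf("non-monotone calibration response for %s", analyte))
  }
  structure(
    list(
      analyte = analyte, slope = slope, intercept = intercept, idl = idl,
      levels = tibble::as_tibble(levels), residuals = unname(stats::resid(fit)),
      monotone = mono
    ),
    class = "calibration_curve"
  )
}

#' Quantify one measurement by isotope dilution
#'
#' Amount ratio = (area_quant/area_eis - intercept)/slope; native mass =
#' ratio x EIS spike; concentration = native mass / sample mass. Negative
#' back-calculated ratios (below-intercept signals) are floored at zero
#' before censoring decisions.
#'
#' @param area_quant,area_eis Peak areas (quantification channel, EIS).
#' @param curve A `calibration_curve`.
#' @param eis_spike EIS amount spiked before extraction (ng).
#' @param sample_mass Sample wet weight (g).
#' @return Raw (pre-censoring) concentration, ng/g; `NA` with a warning if
#'   the EIS area is zero (unquantifiable).
#' @export
quantify <- function(area_quant, area_eis, curve, eis_spike = 4, sample_mass = 0.5) {
  stopifnot(inherits(curve, "calibration_curve"), all(sample_mass > 0))
  n <- length(area_quant)
  area_eis <- rep_len(area_eis, n)
  sample_mass <- rep_len(sample_mass, n)
  eis_spike <- rep_len(eis_spike, n)
  out <- rep(NA_real_, n)
  bad <- !is.finite(area_eis) | area_eis <= 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d measurement(s) with zero EIS area flagged unquantifiable", sum(bad)
    ))
  }
  ratio <- (area_quant[!bad] / area_eis[!bad] - curve$intercept) / curve$slope
  out[!bad] <- pmax(0, ratio) * eis_spike[!bad] / sample_mass[!bad]
  out
}

#' Method detection limit from procedural blanks
#'
#' With two or more blank detects: mean blank concentration plus three
#' times the sample standard deviation. With no detects the instrumental
#' detection limit (IDL) is used. Exactly one detect leaves the SD
#' undefined: falls back to the IDL with a warning.
#'
#' @param blank_concentrations Blank concentrations (ng/g); only values
#'   above `detect_floor` count as detects.
#' @param idl Instrumental detection limit (ng/g).
#' @param detect_floor Numerical-zero threshold (ng/g): back-calculated
#'   blank values at or below it are treated as no signal. The default
#'   1e-9 ng/g is far below any real signal and guards against
#'   floating-point dust from the calibration intercept.
#' @return MDL in ng/g (> 0).
#' @export
compute_mdl <- function(blank_concentrations, idl, detect_floor = 1e-9) {
  detects <- blank_concentrations[!is.na(blank_concentrations) &
    blank_concentrations > detect_floor]
  if (length(detects) >= 2) {
    mdl <- mean(detects) + 3 * stats::sd(detects)
  } else if (length(detects) == 1) {
    rlang::warn("single blank detect: SD undefined, falling back to IDL")
    mdl <- idl
  } else {
    mdl <- idl
  }
  if (!is.finite(mdl) || mdl <= 0) {
    rlang::abort("MDL must be positive; check blanks and IDL",
      class = "hepapfas_qc_error"
    )
  }
  mdl
}

#' Blank-correct a raw concentration with MDL gating
#'
#' Correction is applied only when the raw value exceeds the MDL; a value
#' at or below the MDL, or one that falls to or below the MDL after
#' subtracting the mean blank, is censored (reported as non-detect, never
#' negative).
#'
#' @param raw_conc Raw concentration(s), ng/g.
#' @param blank_mean Mean blank concentration, ng/g.
#' @param mdl Method detection limit, ng/g.
#' @return Tibble with `conc` (`NA` when censored), `mdl`, `censored`,
#'   `blank_corrected`.
#' @export
blank_correct <- function(raw_conc, blank_mean, mdl) {
  stopifnot(mdl > 0, blank_mean >= 0)
  corrected <- raw_conc - blank_mean
  detected <- !is.na(raw_conc) & raw_conc > mdl & corrected > mdl
  tibble::tibble(
    conc = ifelse(detected, corrected, NA_real_),
    mdl = mdl,
    censored = !detected,
    blank_corrected = detected & blank_mean > 0
  )
}

#' Retention-time window check
#'
#' When the EIS is the analyte's own isotopologue (same structure), the
#' analyte-EIS retention-time difference must not exceed 0.1 min. When
#' the EIS is a structural surrogate, the difference is first corrected by
#' the average analyte-EIS shift observed in the batch CCVs and must not
#' exceed 0.4 min. A missing CCV reference in the different-structure case
#' fails safe.
#'
#' @param rt_analyte,rt_eis Retention times (min).
#' @param same_structure Logical: is the EIS the analyte's isotopologue?
#' @param ccv_shift Mean CCV analyte-EIS shift (min); required when
#'   `same_structure = FALSE`.
#' @param window_same,window_diff Window half-widths (min).
#' @return Logical vector `rt_ok`.
#' @export
rt_check <- function(rt_analyte, rt_eis, same_structure, ccv_shift = NA_real_,
                     window_same = 0.1, window_diff = 0.4) {
  delta <- rt_analyte - rt_eis
  if (same_structure) {
    return(abs(delta) <= window_same)
  }
  if (is.na(ccv_shift)) {
    rlang::warn("no CCV retention-time reference for different-structure EIS: failing check")
    return(rep(FALSE, length(delta)))
  }
  abs(delta - ccv_shift) <= window_diff
}

#' Ion abundance ratio against the batch CCV reference
#'
#' The confirmation/quantification channel area ratio, normalized to the
#' mean of the same ratio in the batch CCVs, offset by one so that zero
#' means no deviation. Acceptance is the closed interval \[-1, 1\].
#'
#' @param area_conf,area_quant Sample channel areas.
#' @param ccv_conf,ccv_quant CCV channel areas (>= 1 CCV, both > 0).
#' @return Tibble with `iar` and `iar_ok`.
#' @export
ion_abundance_ratio <- function(area_conf, area_quant, ccv_conf, ccv_quant) {
  if (length(ccv_quant) < 1 || any(ccv_quant <= 0) || any(ccv_conf < 0)) {
    rlang::abort("need >= 1 CCV with positive channel areas",
      class = "hepapfas_qc_error"
    )
  }
  ccv_mean <- mean(ccv_conf / ccv_quant)
  if (ccv_mean <= 0) {
    rlang::abort("CCV mean channel ratio is zero", class = "hepapfas_qc_error")
  }
  iar <- ifelse(
    is.finite(area_quant) & area_quant > 0,
    (area_conf / area_quant) / ccv_mean - 1,
    NA_real_
  )
  tibble::tibble(iar = iar, iar_ok = !is.na(iar) & iar >= -1 & iar <= 1)
}

#' Extractable internal standard recovery check
#'
#' Recovery is the observed EIS response relative to the expected response
#' at the spike level (by default the mean EIS area in the batch CCVs,
#' where recovery is nominal). Limits are inclusive.
#'
#' @param area_eis Observed EIS area(s).
#' @param expected_area Expected EIS area at the spike level.
#' @param limits Acceptance limits as fractions, default 20--150%.
#' @return Tibble with `eis_recovery` and `recovery_ok`.
#' @export
eis_recovery_check <- function(area_eis, expected_area, limits = c(0.2, 1.5)) {
  stopifnot(length(limits) == 2, limits[1] < limits[2], expected_area > 0)
  recovery <- area_eis / expected_area
  tibble::tibble(
    eis_recovery = recovery,
    recovery_ok = recovery >= limits[1] & recovery <= limits[2]
  )
}

#' Apply QC exclusion logic
#'
#' A record (sample x analyte) failing any of the retention-time, ion
#' abundance ratio, or recovery checks is excluded from the concentration
#' output. A sample is wholly excluded when the fraction of its analytes
#' that failed QC or were not detected exceeds the threshold (default
#' 0.75). Decisions are invariant to record ordering.
#'
#' @param qc_records Tibble with `sample_id`, `analyte`, `rt_ok`,
#'   `iar_ok`, `recovery_ok`, and (optionally) `detected`.
#' @param sample_fail_fraction_threshold Fraction above which a whole
#'   sample is excluded.
#' @return `qc_records` with added `record_excluded`, `sample_excluded`,
#'   `excluded`.
#' @export
apply_exclusions <- function(qc_records, sample_fail_fraction_threshold = 0.75) {
  stopifnot(all(c("sample_id", "analyte", "rt_ok", "iar_ok", "recovery_ok") %in%
    names(qc_records)))
  qc <- tibble::as_tibble(qc_records)
  qc$record_excluded <- !(qc$rt_ok & qc$iar_ok & qc$recovery_ok)
  fail_or_nd <- if ("detected" %in% names(qc)) {
    qc$record_excluded | !qc$detected
  } else {
    qc$record_excluded
  }
  frac <- tapply(fail_or_nd, qc$sample_id, mean)
  qc$sample_excluded <- as.logical(
    frac[qc$sample_id] > sample_fail_fraction_threshold
  )
  qc$excluded <- as.logical(qc$record_excluded | qc$sample_excluded)
  qc
}

#' Quantify a full batch table with QA/QC
#'
#' The batch-level driver: fits/accepts per-analyte calibration, derives
#' per-analyte per-batch MDLs from that batch's procedural blanks (IDL
#' fallback), quantifies specimens, applies blank correction with MDL
#' gating, runs the retention-time, ion-abundance-ratio and EIS-recovery
#' checks against the batch CCVs, and applies the exclusion logic.
#'
#' @param batch Tibble of batch measurements (schema of
#'   [generate_batches()]: `sample_id`, `analyte`, `role`, `area_quant`,
#'   `area_conf`, `area_eis`, `rt_analyte`, `rt_eis`, `sample_mass`,
#'   `eis_spike`, `native_spike`, `batch_id`).
#' @param panel A `pfas_panel` (supplies `eis_structure` per analyte).
#' @param calibration Tibble of calibration levels (`analyte`,
#'   `amount_ratio`, `area_ratio`, `idl`) or a pre-fitted list of
#'   `calibration_curve`s named by analyte.
#' @param recovery_limits EIS recovery acceptance limits.
#' @param sample_fail_fraction_threshold Whole-sample exclusion threshold.
#' @return List with `concentrations` (one row per specimen x analyte:
#'   `sample_id`, `analyte`, `conc`, `mdl`, `censored`, `blank_corrected`,
#'   `excluded`) and `qc` (the full QC report).
#' @export
quantify_batch <- function(batch, panel, calibration,
                           recovery_limits = c(0.2, 1.5),
                           sample_fail_fraction_threshold = 0.75) {
  stopifnot(inherits(panel, "pfas_panel"))
  batch <- tibble::as_tibble(batch)
  analytes <- intersect(panel$name, unique(batch$analyte))

  curves <- if (is.list(calibration) && !is.data.frame(calibration)) {
    calibration
  } else {
    cal <- tibble::as_tibble(calibration)
    out <- lapply(analytes, function(a) {
      fit_calibration(cal[cal$analyte == a, ], analyte = a)
    })
    stats::setNames(out, analytes)
  }

  res_conc <- vector("list", length(analytes))
  res_qc <- vector("list", length(analytes))
  for (i in seq_along(analytes)) {
    a <- analytes[i]
    curve <- curves[[a]]
    same_structure <- panel$eis_structure[panel$name == a] == "same"
    ab <- batch[batch$analyte == a, ]
    out_b <- vector("list", length(unique(ab$batch_id)))
    bids <- sort(unique(ab$batch_id))
    for (k in seq_along(bids)) {
      bb <- ab[ab$batch_id == bids[k], ]
      spec <- bb[bb$role == "specimen", ]
      blanks <- bb[bb$role == "blank", ]
      ccv <- bb[bb$role == "ccv", ]
      if (nrow(spec) == 0) next

      blank_conc <- if (nrow(blanks)) {
        quantify(blanks$area_quant, blanks$area_eis, curve,
          eis_spike = blanks$eis_spike[1], sample_mass = blanks$sample_mass
        )
      } else {
        numeric(0)
      }
      blank_detects <- blank_conc[blank_conc > 1e-9]
      mdl <- compute_mdl(blank_conc, curve$idl)
      blank_mean <- if (length(blank_detects)) mean(blank_detects) else 0

      raw <- quantify(spec$area_quant, spec$area_eis, curve,
        eis_spike = spec$eis_spike[1], sample_mass = spec$sample_mass
      )
      bc <- blank_correct(raw, blank_mean, mdl)

      ccv_shift <- if (nrow(ccv)) mean(ccv$rt_analyte - ccv$rt_eis) else NA_real_
      rt_ok <- rt_check(spec$rt_analyte, spec$rt_eis, same_structure, ccv_shift)
      iar_tb <- if (nrow(ccv)) {
        ion_abundance_ratio(
          spec$area_conf, spec$area_quant, ccv$area_conf, ccv$area_quant
        )
      } else {
        tibble::tibble(
          iar = rep(NA_real_, nrow(spec)),
          iar_ok = rep(FALSE, nrow(spec))
        )
      }
      expected_eis <- if (nrow(ccv)) mean(ccv$area_eis) else mean(spec$area_eis)
      rec <- eis_recovery_check(spec$area_eis, expected_eis, recovery_limits)

      out_b[[k]] <- tibble::tibble(
        sample_id = spec$sample_id, analyte = a, batch_id = bids[k],
        raw_conc = raw, conc = bc$conc, mdl = bc$mdl,
        censored = bc$censored, blank_corrected = bc$blank_corrected,
        rt_ok = rt_ok, iar = iar_tb$iar, iar_ok = iar_tb$iar_ok,
        eis_recovery = rec$eis_recovery, recovery_ok = rec$recovery_ok,
        detected = !bc$censored
      )
    }
    res_qc[[i]] <- dplyr::bind_rows(out_b)
  }
  qc <- dplyr::bind_rows(res_qc)
  qc <- apply_exclusions(qc, sample_fail_fraction_threshold)
  conc <- qc[!qc$excluded, c(
    "sample_id", "analyte", "conc", "mdl", "censored", "blank_corrected"
  )]
  list(concentrations = conc, qc = qc)
}
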