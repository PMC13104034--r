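# Extractable organofluorine (EOF) mass balance: blank correction and MDL
# for combustion-IC fluoride readings, conversion of targeted PFAS
# concentrations to fluorine equivalents via the registry's fluorine mass
# fractions, and the fraction-of-EOF-explained computation.

#' Blank-correct an EOF reading
#'
#' Readings exceeding the batch DI-water procedural-blank mean are
#' corrected by subtracting it; readings at or below the blank mean floor
#' at zero (flagged), never negative.
#'
#' @param reading Fluoride reading(s), ng F/g wet weight.
#' @param di_blank_mean Mean of the batch's DI-water procedural blanks
#'   (requires at least one blank).
#' @return Tibble with `eof` (corrected, ng F/g) and `below_background`.
#' @export
eof_blank_correct <- function(reading, di_blank_mean) {
  if (length(di_blank_mean) != 1 || is.na(di_blank_mean)) {
    rlang::abort("no DI-water blanks available for this batch",
      class = "hepapfas_eof_error"
    )
  }
  corrected <- reading - di_blank_mean
  tibble::tibble(
    eof = pmax(0, corrected),
    below_background = corrected <= 0
  )
}

#' EOF method detection limit
#'
#' Three times the sample standard deviation of the matrix extraction
#' blanks, scaled by the dilution factor. Requires at least two blanks.
#'
#' @param matrix_blanks Matrix-extraction blank readings (>= 2), ng F/g.
#' @param dilution_factor Dilution factor (>= 1).
#' @return MDL, ng F/g. Scales linearly with the dilution factor.
#' @export
eof_mdl <- function(matrix_blanks, dilution_factor = 1) {
  matrix_blanks <- matrix_blanks[!is.na(matrix_blanks)]
  if (length(matrix_blanks) < 2) {
    rlang::abort("EOF MDL requires >= 2 matrix extraction blanks",
      class = "hepapfas_eof_error"
    )
  }
  stopifnot(dilution_factor >= 1)
  3 * stats::sd(matrix_blanks) * dilution_factor
}

#' Convert targeted concentrations to a fluorine-equivalent sum
#'
#' Sum over analytes of concentration times the analyte's fluorine mass
#' fraction, giving ng F/g for direct comparison with EOF. Censored
#' analytes contribute zero by default (a conservative lower bound on the
#' explained fraction) or MDL/2 when `censored_mode = "half_mdl"`. Linear
#' in the concentrations.
#'
#' @param concentrations Tibble with `analyte`, `conc`, `censored`,
#'   `mdl` for one sample (or pre-filtered to one sample).
#' @param panel A `pfas_panel` resolving every analyte.
#' @param censored_mode `"zero"` or `"half_mdl"`.
#' @return Fluorine-equivalent sum, ng F/g.
#' @export
targeted_fluorine_equivalent <- function(concentrations, panel,
                                         censored_mode = c("zero", "half_mdl")) {
  censored_mode <- match.arg(censored_mode)
  cc <- tibble::as_tibble(concentrations)
  idx <- match(cc$analyte, panel$name)
  if (anyNA(idx)) {
    rlang::abort(
      sprintf(
        "analyte(s) not in panel: %s",
        paste(unique(cc$analyte[is.na(idx)]), collapse = ", ")
      ),
      class = "hepapfas_eof_error"
    )
  }
  ffrac <- vapply(panel$formula[idx], fluorine_mass_fraction, numeric(1))
  value <- ifelse(cc$censored,
    if (censored_mode == "half_mdl") cc$mdl / 2 else 0,
    cc$conc
  )
  sum(value * ffrac, na.rm = TRUE)
}

#' EOF mass balance
#'
#' Fraction of EOF explained by the targeted fluorine-equivalent sum,
#' the unexplained remainder, and the EOF/targeted fold gap. A targeted
#' sum exceeding the EOF yields a fraction above 100% with a data-quality
#' warning (not an error).
#'
#' @param eof Blank-corrected EOF, ng F/g (> 0).
#' @param targeted_f Targeted fluorine-equivalent sum, ng F/g.
#' @return Tibble with `eof`, `targeted_f`, `fraction_explained`
#'   (percent), `unexplained` (ng F/g, `NA` when the balance overshoots),
#'   `fold_gap` (`NA` when `targeted_f` is 0).
#' @export
mass_balance <- function(eof, targeted_f) {
  stopifnot(all(eof > 0), all(targeted_f >= 0))
  if (any(targeted_f > eof)) {
    rlang::warn("targeted fluorine exceeds EOF for >= 1 sample: fraction > 100% (data-quality flag)")
  }
  tibble::tibble(
    eof = eof,
    targeted_f = targeted_f,
    fraction_explained = 100 * targeted_f / eof,
    unexplained = ifelse(targeted_f <= eof, eof - targeted_f, NA_real_),
    fold_gap = ifelse(targeted_f > 0, eof / targeted_f, NA_real_)
  )
}

#' Run the EOF mass balance for a measurement table
#'
#' Blank-corrects specimen readings against the batch DI blanks, computes
#' the batch EOF MDL from matrix blanks, joins the targeted
#' fluorine-equivalent sums by donor id, and returns the per-sample mass
#' balance.
#'
#' @param eof_measurements Tibble with `sample_id`, `fluoride_reading`,
#'   `batch_id`, `dilution_factor`, `role`
#'   (specimen/di_blank/matrix_blank/...).
#' @param concentrations Quantified concentration records (`sample_id`,
#'   `analyte`, `conc`, `censored`, `mdl`).
#' @param panel A `pfas_panel`.
#' @param censored_mode Passed to [targeted_fluorine_equivalent()].
#' @return Tibble: one row per specimen with `sample_id`, `eof`,
#'   `eof_mdl`, `targeted_f`, `fraction_explained`, `unexplained`,
#'   `fold_gap`.
#' @export
run_mass_balance <- function(eof_measurements, concentrations, panel,
                             censored_mode = c("zero", "half_mdl")) {
  censored_mode <- match.arg(censored_mode)
  em <- tibble::as_tibble(eof_measurements)
  out <- lapply(split(em, em$batch_id), function(b) {
    spec <- b[b$role == "specimen", ]
    if (nrow(spec) == 0) {
      return(NULL)
    }
    di <- b$fluoride_reading[b$role == "di_blank"]
    mx <- b$fluoride_reading[b$role == "matrix_blank"]
    bc <- eof_blank_correct(spec$fluoride_reading, mean(di))
    mdl <- eof_mdl(mx, spec$dilution_factor[1])
    tf <- vapply(spec$sample_id, function(id) {
      cc <- concentrations[concentrations$sample_id == id, ]
      if (nrow(cc) == 0) {
        return(NA_real_)
      }
      targeted_fluorine_equivalent(cc, panel, censored_mode)
    }, numeric(1))
    keep <- bc$eof > 0 & !is.na(tf)
    mb <- mass_balance(bc$eof[keep], tf[keep])
    tibble::tibble(
      sample_id = spec$sample_id[keep], eof_mdl = mdl, mb
    )
  })
  dplyr::bind_rows(out)
}
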