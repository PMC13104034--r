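# Cohort-table assembly and censored-data summaries. The cohort table is a
# long tibble (one row per donor x analyte) carrying each concentration
# with its MDL and censoring flag, joined to the donor covariates; it is
# the substrate for all downstream statistics.

#' Resolve a reported collection date to a numeric year
#'
#' Exact years pass through; date ranges resolve to their midpoint (e.g.
#' 2000--2005 becomes 2002.5); missing dates stay missing and the donor is
#' excluded from year-dependent analyses downstream.
#'
#' @param year_exact Exact year or `NA`.
#' @param year_start,year_end Range endpoints or `NA`.
#' @return Numeric year or `NA`. Vectorised.
#' @export
resolve_year <- function(year_exact, year_start = NA_real_, year_end = NA_real_) {
  n <- max(length(year_exact), length(year_start), length(year_end))
  year_exact <- rep_len(year_exact, n)
  year_start <- rep_len(year_start, n)
  year_end <- rep_len(year_end, n)
  has_range <- !is.na(year_start) & !is.na(year_end)
  if (any(has_range & year_end < year_start)) {
    rlang::abort("reversed year range (end < start)", class = "hepapfas_data_error")
  }
  out <- ifelse(!is.na(year_exact), year_exact,
    ifelse(has_range, (year_start + year_end) / 2, NA_real_)
  )
  out
}

#' Assemble the donor x analyte cohort table
#'
#' Joins quantified (blank-corrected, possibly censored) concentrations to
#' donor metadata and resolves collection dates via [resolve_year()].
#'
#' @param concentrations Tibble from [quantify_batch()] (`sample_id`,
#'   `analyte`, `conc`, `mdl`, `censored`) where `sample_id` is the donor
#'   id.
#' @param donors Donor metadata (`donor_id`, `age`, `sex`, `health`,
#'   `year_exact`, `year_start`, `year_end`).
#' @return A `pfas_cohort` tibble (long: donor x analyte) with a resolved
#'   `year` column.
#' @export
build_cohort <- function(concentrations, donors) {
  conc <- tibble::as_tibble(concentrations)
  donors <- tibble::as_tibble(donors)
  stopifnot(
    all(c("sample_id", "analyte", "conc", "mdl", "censored") %in% names(conc)),
    all(c("donor_id", "age", "sex", "health") %in% names(donors))
  )
  if (anyDuplicated(donors$donor_id)) {
    rlang::abort("duplicate donor_id in donor metadata", class = "hepapfas_data_error")
  }
  donors$year <- resolve_year(
    donors$year_exact %||% NA_real_,
    donors$year_start %||% NA_real_, donors$year_end %||% NA_real_
  )
  donors$year_is_exact <- !is.na(donors$year_exact %||% NA_real_)
  out <- dplyr::inner_join(
    dplyr::rename(conc, donor_id = "sample_id"),
    donors[, c(
      "donor_id", "age", "sex", "health", "year", "year_is_exact"
    )],
    by = "donor_id"
  )
  class(out) <- c("pfas_cohort", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Substitute nondetects at MDL/2
#'
#' Censored cells are replaced by half their method detection limit (the
#' expected value under a uniform distribution between zero and the MDL);
#' detected cells are unchanged. The censoring flag is retained as
#' `substituted`.
#'
#' @param table A `pfas_cohort` (or any tibble with `conc`, `mdl`,
#'   `censored`).
#' @return The table with a numeric `value` column and a `substituted`
#'   flag.
#' @export
substitute_nondetects <- function(table) {
  stopifnot(all(c("conc", "mdl", "censored") %in% names(table)))
  bad <- table$censored & (is.na(table$mdl) | table$mdl <= 0)
  if (any(bad)) {
    rlang::abort(
      sprintf("%d censored cell(s) with missing or non-positive MDL", sum(bad)),
      class = "hepapfas_data_error"
    )
  }
  table$value <- ifelse(table$censored, table$mdl / 2, table$conc)
  table$substituted <- table$censored
  table
}

#' Per-analyte detection frequency
#'
#' @param table A `pfas_cohort`.
#' @return Tibble with `analyte`, `n_donors`, `n_detects`,
#'   `detection_frequency` (percent, unrounded).
#' @export
detection_frequency <- function(table) {
  stopifnot(nrow(table) > 0)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(table), .data$analyte),
    n_donors = dplyr::n(),
    n_detects = sum(!.data$censored),
    detection_frequency = 100 * .data$n_detects / .data$n_donors,
    .groups = "drop"
  )
}

#' Per-donor summed PFAS concentration
#'
#' `detected_only` sums only uncensored values (the convention for
#' log-scale trend plots; donors with no detects get a zero sum and are
#' dropped from log-scale analyses with a warning downstream).
#' `substituted` sums MDL/2-filled values (the regression input) and is
#' always >= the detected-only sum.
#'
#' @param table A `pfas_cohort`.
#' @param mode `"detected_only"` or `"substituted"`.
#' @return Tibble with `donor_id`, covariates, and `sum_pfas` (ng/g).
#' @export
sum_pfas <- function(table, mode = c("detected_only", "substituted")) {
  mode <- match.arg(mode)
  tb <- tibble::as_tibble(table)
  if (mode == "substituted") {
    tb <- substitute_nondetects(tb)
    tb$term <- tb$value
  } else {
    tb$term <- ifelse(tb$censored, 0, tb$conc)
  }
  covars <- intersect(c("age", "sex", "health", "year", "year_is_exact"), names(tb))
  dplyr::summarise(
    dplyr::group_by(tb, dplyr::across(dplyr::all_of(c("donor_id", covars)))),
    sum_pfas = sum(.data$term, na.rm = TRUE),
    n_detected = sum(!.data$censored),
    .groups = "drop"
  )
}

#' Chemical-class composition by year
#'
#' For each requested year: per-donor class sums (censored cells
#' contribute zero), averaged across that year's donors, then normalized
#' so the class shares sum to 100%.
#'
#' @param table A `pfas_cohort`.
#' @param panel A `pfas_panel` giving each analyte's class.
#' @param years Years to summarise; defaults to all exact years present.
#' @return Tibble with `year`, `class`, `mean_conc` (ng/g), `share`
#'   (percent; sums to 100 per year). Years with no samples yield no rows.
#' @export
class_composition <- function(table, panel, years = NULL) {
  tb <- tibble::as_tibble(table)
  tb <- tb[!is.na(tb$year), ]
  tb$class <- panel$class[match(tb$analyte, panel$name)]
  if (anyNA(tb$class)) {
    rlang::abort("analyte(s) in cohort not present in panel",
      class = "hepapfas_data_error"
    )
  }
  if (is.null(years)) years <- sort(unique(tb$year[tb$year_is_exact]))
  tb <- tb[tb$year %in% years, ]
  if (nrow(tb) == 0) {
    return(tibble::tibble(
      year = numeric(), class = character(),
      mean_conc = numeric(), share = numeric()
    ))
  }
  tb$term <- ifelse(tb$censored, 0, tb$conc)
  by_donor <- dplyr::summarise(
    dplyr::group_by(tb, .data$year, .data$donor_id, .data$class),
    class_sum = sum(.data$term, na.rm = TRUE), .groups = "drop"
  )
  by_year <- dplyr::summarise(
    dplyr::group_by(by_donor, .data$year, .data$class),
    mean_conc = mean(.data$class_sum), .groups = "drop"
  )
  dplyr::mutate(
    dplyr::group_by(by_year, .data$year),
    share = 100 * .data$mean_conc / sum(.data$mean_conc)
  ) |> dplyr::ungroup()
}

#' Period summary of summed PFAS
#'
#' Median, interquartile range, extremes and fold range (max/min) of the
#' per-donor summed PFAS within year periods. Quantiles use linear
#' interpolation. A period minimum of zero leaves the fold range
#' undefined (`NA`).
#'
#' @param sums Tibble from [sum_pfas()] (needs `sum_pfas` and `year`), or
#'   a bare numeric vector of sums (then `periods` is ignored and a single
#'   summary is returned).
#' @param periods Named list of `c(start, end)` year ranges; defaults to
#'   the early-2000s / late-2000s / 2020s comparison bins.
#' @return Tibble with `period`, `n`, `median`, `q1`, `q3`, `min`, `max`,
#'   `fold_range`.
#' @export
period_summary <- function(sums,
                           periods = list(
                             "2000-2005" = c(2000, 2005),
                             "2006-2010" = c(2006, 2010),
                             "2020-2024" = c(2020, 2024)
                           )) {
  summarise_one <- function(x, label) {
    x <- x[!is.na(x)]
    stopifnot(length(x) >= 1)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(
      period = label, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
      min = min(x), max = max(x),
      fold_range = if (min(x) > 0) max(x) / min(x) else NA_real_
    )
  }
  if (is.numeric(sums)) {
    return(summarise_one(sums, "all"))
  }
  stopifnot(all(c("sum_pfas", "year") %in% names(sums)))
  out <- lapply(names(periods), function(nm) {
    rng <- periods[[nm]]
    x <- sums$sum_pfas[!is.na(sums$year) & sums$year >= rng[1] & sums$year <= rng[2]]
    if (!length(x)) {
      return(NULL)
    }
    summarise_one(x, nm)
  })
  dplyr::bind_rows(out)
}
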