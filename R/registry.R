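#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Standard atomic masses (IUPAC 2021 abridged, 3 decimals). The panel only
# needs the elements that occur in per- and polyfluoroalkyl acids and their
# sulfonamide/ether relatives.
ATOMIC_MASSES <- c(
  C = 12.011, H = 1.008, F = 18.998, N = 14.007,
  O = 15.999, S = 32.06, Cl = 35.45
)

PFAS_CLASSES <- c(
  "PFCA", "PFSA", "FTCA", "FTS", "FOSAA",
  "chlorinated_ether", "PFECA", "cyclic_PFSA"
)

ISOMER_LEVELS <- c("linear", "branched", "total")

#' Parse a Hill-notation molecular formula
#'
#' Converts a condensed formula string such as `"C8HF15O2"` into a named
#' count vector. Only the elements occurring in the PFAS panel chemistry
#' (C, H, F, N, O, S, Cl) are accepted; anything else is a configuration
#' error, not a silent drop.
#'
#' @param formula A single formula string, e.g. `"C8HF15O2"`.
#' @return Named numeric vector of element counts.
#' @examples
#' parse_formula("C8HF15O2")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) {
    abort("empty formula", class = "hepapfas_config_error")
  }
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(matches))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    abort(
      sprintf("formula '%s' contains unparseable characters", formula),
      class = "hepapfas_config_error"
    )
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
    sub("^[A-Za-z]+", "", tokens), "1"
  ))
  unknown <- setdiff(elems, names(ATOMIC_MASSES))
  if (length(unknown)) {
    abort(
      sprintf(
        "unknown element symbol(s) in '%s': %s",
        formula, paste(unknown, collapse = ", ")
      ),
      class = "hepapfas_config_error"
    )
  }
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  stats::setNames(as.numeric(out), names(out))
}

as_formula_counts <- function(formula) {
  if (is.character(formula)) {
    return(parse_formula(formula))
  }
  if (is.numeric(formula) && !is.null(names(formula))) {
    unknown <- setdiff(names(formula), names(ATOMIC_MASSES))
    if (length(unknown)) {
      abort(
        sprintf("unknown element symbol(s): %s", paste(unknown, collapse = ", ")),
        class = "hepapfas_config_error"
      )
    }
    return(formula)
  }
  abort("formula must be a string or a named count vector",
    class = "hepapfas_config_error"
  )
}

#' Molecular weight of an analyte formula
#'
#' @param formula Formula string (e.g. `"C4HF7O2"`) or named element-count
#'   vector.
#' @param form `"neutral"` (free acid, default) or `"anion"` (deprotonated;
#'   one hydrogen removed). Fluorine mass fractions differ by ~0.2% between
#'   the two conventions.
#' @return Mass in g/mol.
#' @examples
#' molecular_weight("C4HF7O2") # PFBA, ~214 g/mol
#' @export
molecular_weight <- function(formula, form = c("neutral", "anion")) {
  form <- match.arg(form)
  counts <- as_formula_counts(formula)
  if (!length(counts)) {
    abort("empty formula", class = "hepapfas_config_error")
  }
  if (form == "anion") {
    h <- counts["H"]
    if (is.na(h) || h < 1) {
      abort("anion form requires at least one hydrogen to remove",
        class = "hepapfas_config_error"
      )
    }
    counts["H"] <- h - 1
  }
  sum(counts * ATOMIC_MASSES[names(counts)])
}

#' Fluorine mass fraction of an analyte
#'
#' The fraction of molecular mass contributed by fluorine,
#' `n_F * 18.998 / MW`. This is the conversion factor used to express
#' targeted PFAS concentrations as fluorine equivalents (ng F/g) for
#' comparison with extractable organofluorine.
#'
#' @inheritParams molecular_weight
#' @return Fraction in (0, 1].
#' @examples
#' fluorine_mass_fraction("C8HF15O2") # PFOA, ~0.688
#' @export
fluorine_mass_fraction <- function(formula, form = c("neutral", "anion")) {
  form <- match.arg(form)
  counts <- as_formula_counts(formula)
  nf <- counts["F"]
  if (is.na(nf) || nf < 1) {
    abort("formula contains no fluorine: not a PFAS",
      class = "hepapfas_config_error"
    )
  }
  unname(nf * ATOMIC_MASSES[["F"]] / molecular_weight(counts, form = form))
}

#' Construct and validate an analyte panel
#'
#' A panel is a tibble with one row per analyte and the columns
#' `name`, `class`, `formula`, `n_pfc`, `isomer`, `eis_name`,
#' `eis_structure` (`"same"`/`"different"` — whether the assigned
#' extractable internal standard is the isotopologue of the analyte or a
#' structural surrogate, which controls the retention-time window rule)
#' and `rt` (nominal retention time, minutes). Internal-standard name
#' lists are carried as attributes `eis_list` / `nis_list`.
#'
#' @param analytes Data frame of analytes with the columns above.
#' @param eis_list Character vector of extractable internal standards;
#'   defaults to the unique `eis_name` values.
#' @param nis_list Character vector of non-extracted (injection) internal
#'   standards.
#' @return A `pfas_panel` tibble.
#' @export
pfas_panel <- function(analytes, eis_list = NULL, nis_list = character()) {
  panel <- as_tibble(analytes)
  required <- c("name", "class", "formula", "n_pfc", "isomer", "eis_name")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    abort(
      sprintf("panel is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      class = "hepapfas_config_error"
    )
  }
  if (!"eis_structure" %in% names(panel)) panel$eis_structure <- "same"
  if (!"rt" %in% names(panel)) panel$rt <- seq(1.5, 6, length.out = nrow(panel))
  if (anyDuplicated(panel$name)) {
    abort("analyte names must be unique", class = "hepapfas_config_error")
  }
  bad_class <- setdiff(unique(panel$class), PFAS_CLASSES)
  if (length(bad_class)) {
    abort(
      sprintf(
        "unclassified analyte class(es): %s (known: %s)",
        paste(bad_class, collapse = ", "), paste(PFAS_CLASSES, collapse = ", ")
      ),
      class = "hepapfas_config_error"
    )
  }
  if (!all(panel$isomer %in% ISOMER_LEVELS)) {
    abort("isomer must be one of linear/branched/total",
      class = "hepapfas_config_error"
    )
  }
  if (!all(panel$eis_structure %in% c("same", "different"))) {
    abort("eis_structure must be 'same' or 'different'",
      class = "hepapfas_config_error"
    )
  }
  for (i in seq_len(nrow(panel))) {
    counts <- parse_formula(panel$formula[i])
    nf <- counts["F"]
    if (is.na(nf) || nf < 1) {
      abort(
        sprintf("analyte %s has no fluorine in its formula", panel$name[i]),
        class = "hepapfas_config_error"
      )
    }
    nc <- counts["C"]
    if (is.na(panel$n_pfc[i]) || panel$n_pfc[i] < 1 ||
      is.na(nc) || panel$n_pfc[i] > nc) {
      abort(
        sprintf(
          "analyte %s: n_pfc must lie in [1, carbon count]",
          panel$name[i]
        ),
        class = "hepapfas_config_error"
      )
    }
  }
  if (is.null(eis_list)) eis_list <- unique(panel$eis_name)
  unresolved <- setdiff(panel$eis_name, eis_list)
  if (length(unresolved)) {
    abort(
      sprintf(
        "eis_name(s) not in the panel's internal-standard list: %s",
        paste(unresolved, collapse = ", ")
      ),
      class = "hepapfas_config_error"
    )
  }
  attr(panel, "eis_list") <- eis_list
  attr(panel, "nis_list") <- nis_list
  class(panel) <- c("pfas_panel", class(panel))
  panel
}

#' Default liver-panel configuration
#'
#' A representative panel of the ~29 analytes (branched and linear isomers
#' separate) reported as detected in banked human liver tissue: legacy
#' perfluoroalkyl carboxylates and sulfonates, perfluorooctanesulfonamide
#' precursors, chlorinated polyfluoroether sulfonates (F-53B components),
#' a perfluoroether carboxylate, a cyclic sulfonate, and fluorotelomer
#' acids/sulfonates. Formulas are neutral (free-acid) forms. `n_pfc`
#' follows the source reporting convention per analyte. Internal-standard
#' assignments and nominal retention times are synthetic defaults standing
#' in for an instrument-specific method table.
#'
#' @return A `pfas_panel` tibble.
#' @export
default_panel <- function() {
  df <- tibble::tribble(
    ~name, ~class, ~formula, ~n_pfc, ~isomer, ~eis_name, ~eis_structure, ~rt,
    "PFBA", "PFCA", "C4HF7O2", 3, "total", "M4PFBA", "same", 1.2,
    "PFHxA", "PFCA", "C6HF11O2", 5, "total", "M5PFHxA", "same", 2.0,
    "PFHpA", "PFCA", "C7HF13O2", 6, "total", "M4PFHpA", "same", 2.5,
    "PFOA", "PFCA", "C8HF15O2", 7, "total", "M8PFOA", "same", 3.0,
    "PFNA", "PFCA", "C9HF17O2", 8, "total", "M9PFNA", "same", 3.5,
    "PFDA", "PFCA", "C10HF19O2", 9, "total", "M6PFDA", "same", 4.0,
    "PFUdA", "PFCA", "C11HF21O2", 11, "total", "M7PFUdA", "same", 4.5,
    "PFDoA", "PFCA", "C12HF23O2", 12, "total", "M2PFDoA", "same", 5.0,
    "PFTrDA", "PFCA", "C13HF25O2", 13, "total", "M2PFTeDA", "different", 5.4,
    "PFTeDA", "PFCA", "C14HF27O2", 14, "total", "M2PFTeDA", "same", 5.8,
    "L-PFHxS", "PFSA", "C6HF13O3S", 6, "linear", "M3PFHxS", "same", 2.8,
    "Br-PFHxS", "PFSA", "C6HF13O3S", 6, "branched", "M3PFHxS", "different", 2.7,
    "PFHpS", "PFSA", "C7HF15O3S", 7, "total", "M8PFOS", "different", 3.3,
    "L-PFOS", "PFSA", "C8HF17O3S", 8, "linear", "M8PFOS", "same", 3.8,
    "Br-PFOS", "PFSA", "C8HF17O3S", 8, "branched", "M8PFOS", "different", 3.7,
    "PFDS", "PFSA", "C10HF21O3S", 10, "total", "M8PFOS", "different", 4.7,
    "FOSA", "FOSAA", "C8H2F17NO2S", 8, "total", "M8FOSA", "same", 4.2,
    "L-N-MeFOSAA", "FOSAA", "C11H6F17NO4S", 8, "linear", "d3-N-MeFOSAA", "same", 4.0,
    "Br-N-MeFOSAA", "FOSAA", "C11H6F17NO4S", 8, "branched", "d3-N-MeFOSAA", "different", 3.9,
    "L-N-EtFOSAA", "FOSAA", "C12H8F17NO4S", 8, "linear", "d5-N-EtFOSAA", "same", 4.3,
    "9Cl-PF3ONS", "chlorinated_ether", "C8HClF16O4S", 8, "total", "M8PFOS", "different", 4.1,
    "11Cl-PF3OUdS", "chlorinated_ether", "C10HClF20O4S", 10, "total", "M8PFOS", "different", 5.0,
    "3,6-OPFHpA", "PFECA", "C5HF9O4", 4, "total", "M3HFPO-DA", "different", 1.8,
    "PFECHS", "cyclic_PFSA", "C8HF15O3S", 8, "total", "M8PFOS", "different", 3.6,
    "6:2 FTS", "FTS", "C8H5F13O3S", 6, "total", "M2-6:2FTS", "same", 3.1,
    "8:2 FTS", "FTS", "C10H5F17O3S", 8, "total", "M2-8:2FTS", "same", 4.05,
    "10:2 FTS", "FTS", "C12H5F21O3S", 10, "total", "M2-8:2FTS", "different", 4.9,
    "7:3 FTCA", "FTCA", "C10H5F15O2", 7, "total", "M2-7:3FTCA", "same", 3.95,
    "5:3 FTCA", "FTCA", "C8H5F11O2", 5, "total", "M2-7:3FTCA", "different", 2.9
  )
  pfas_panel(df, nis_list = c("M2PFHxA-NIS", "M4PFOS-NIS"))
}

#' Read / write a panel configuration CSV
#'
#' The CSV schema mirrors the panel columns (`name, class, formula, n_pfc,
#' isomer, eis_name, eis_structure, rt`); formulas are Hill-notation
#' strings.
#'
#' @param path File path.
#' @return `read_panel()` returns a validated `pfas_panel`.
#' @export
read_panel <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pfas_panel(df)
}

#' @rdname read_panel
#' @param panel A `pfas_panel`.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(as_tibble(panel), path)
  invisible(path)
}
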