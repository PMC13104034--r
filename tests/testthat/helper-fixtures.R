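# Shared fixtures: all built in code at test time.

# Simulation settings with every instrument noise source switched off, so
# the quantification round trip is exact. Residual biological variation
# (sigma) stays configurable.
zero_noise_sim <- function(n_donors = 30, seed = 1, sigma = 0, ...) {
  p <- sim_params(n_donors = n_donors, seed = seed, ...)
  p$instrument$area_cv <- 0
  p$instrument$recovery_sd <- 0
  p$instrument$channel_ratio_sd <- 0
  p$instrument$rt_jitter_sd <- 0
  p$instrument$sample_mass_sd <- 0
  p$analytes$sigma <- sigma
  p$analytes$blank_ng_mean <- 0
  p$analytes$blank_ng_sd <- 0
  p$analytes$idl <- 1e-10
  p
}

# Minimal hand-built cohort table (long, one row per donor x analyte) for
# dataset/trend/MLR tests that don't need the instrument model.
toy_cohort <- function(donors, analytes, conc, censored = NULL, mdl = 0.05) {
  grid <- expand.grid(
    donor_id = donors$donor_id, analyte = analytes,
    stringsAsFactors = FALSE
  )
  tb <- tibble::as_tibble(grid)
  tb$conc <- conc
  tb$censored <- if (is.null(censored)) rep(FALSE, nrow(tb)) else censored
  tb$conc[tb$censored] <- NA_real_
  tb$mdl <- mdl
  out <- dplyr::left_join(tb, donors, by = "donor_id")
  if (!"year_is_exact" %in% names(out)) out$year_is_exact <- !is.na(out$year)
  class(out) <- c("pfas_cohort", class(out))
  out
}

# Simple exact calibration curve for unit tests.
unit_curve <- function(slope = 1, intercept = 0, idl = 0.01) {
  levels <- data.frame(amount_ratio = c(0.05, 0.25, 0.5, 1, 2, 5))
  levels$area_ratio <- slope * levels$amount_ratio + intercept
  fit_calibration(levels, analyte = "test", idl = idl)
}
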