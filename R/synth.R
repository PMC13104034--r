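# Synthetic liver-cohort generator. Emulates the statistical structure the
# downstream analysis assumes: a donor cohort with the banked-specimen
# demographics (age ~ truncated normal 57.5 +/- 13.5 on [18, 85], balanced
# sex, ~54% NAFLD with prevalence rising over collection years so that the
# squared year-health correlation hits a configurable target), true
# log-normal tissue concentrations driven by year/age/sex/health effects,
# and batch-level instrument records (peak areas, internal standards,
# blanks, CCVs, positive controls) that the quantification stage consumes.

#' Simulation parameters for the synthetic liver cohort
#'
#' Bundles the cohort-level, analyte-level and instrument-level settings of
#' the generator. Defaults reproduce the study conditions the analysis is
#' designed for: 211 donors, age mean 57.51 / SD 13.53 truncated to 18--85,
#' a 50/50 sex split with ~85% of females aged 46+, 54% NAFLD prevalence
#' with a year--health squared correlation of 0.43, collection years
#' 2000--2024 with unequal per-year counts, and ~84% exact / 14% ranged /
#' 1.4% missing collection dates.
#'
#' @param n_donors Number of donors.
#' @param seed Integer seed; fixed seed + params give byte-identical output.
#' @param panel A `pfas_panel`; defaults to [default_panel()].
#' @param analytes Per-analyte effect table as produced by
#'   [default_sim_analytes()]: columns `analyte`, `log10_c0` (baseline
#'   log10 ng/g at year 2000), `beta_year` (log10 units per decade),
#'   `beta_age` (log10 units per decade of age), `beta_sex` (female -
#'   male), `beta_health` (NAFLD - normal), `sigma` (residual SD, log10),
#'   `idl` (instrumental detection limit, ng/g), `blank_ng_mean`,
#'   `blank_ng_sd` (procedural-blank contamination, ng).
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age model.
#' @param p_female Bernoulli probability of female sex.
#' @param female_postmeno_frac Fraction of female donors drawn at age >= 46.
#' @param nafld_frac Marginal NAFLD prevalence.
#' @param year_health_r2 Target squared correlation between collection year
#'   and NAFLD status (0 disables the year dependence).
#' @param years,year_weights Candidate collection years and their unequal
#'   sampling weights.
#' @param p_year_exact,p_year_range,p_year_missing Probabilities that a
#'   donor's collection date is reported as an exact year, a year range, or
#'   missing. Ranges span `range_width` years around the latent true year.
#' @param range_width Width (years) of reported date ranges.
#' @param p_health_missing,p_age_missing,p_bmi_missing Metadata gap rates.
#' @param instrument List of instrument/noise settings; see
#'   [default_instrument_params()].
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_donors = 211,
                       seed = 1L,
                       panel = default_panel(),
                       analytes = default_sim_analytes(panel),
                       age_mean = 57.51, age_sd = 13.53,
                       age_min = 18, age_max = 85,
                       p_female = 0.5,
                       female_postmeno_frac = 90 / 106,
                       nafld_frac = 0.54,
                       year_health_r2 = 0.43,
                       years = 2000:2024,
                       year_weights = default_year_weights(),
                       p_year_exact = 178 / 211,
                       p_year_range = 30 / 211,
                       p_year_missing = 3 / 211,
                       range_width = 5,
                       p_health_missing = 2 / 211,
                       p_age_missing = 1 / 211,
                       p_bmi_missing = 93 / 211,
                       instrument = default_instrument_params()) {
  stopifnot(
    n_donors >= 0, age_sd > 0, age_min < age_max,
    p_female >= 0, p_female <= 1,
    nafld_frac >= 0, nafld_frac <= 1,
    year_health_r2 >= 0, year_health_r2 < 1,
    length(years) == length(year_weights), all(year_weights >= 0),
    abs(p_year_exact + p_year_range + p_year_missing - 1) < 1e-8
  )
  if (any(analytes$sigma < 0)) {
    rlang::abort("residual SD sigma must be >= 0", class = "hepapfas_config_error")
  }
  if (any(unlist(instrument[grepl("_cv$|_sd$", names(instrument))]) < 0)) {
    rlang::abort("noise CVs/SDs must be >= 0", class = "hepapfas_config_error")
  }
  structure(
    list(
      n_donors = n_donors, seed = as.integer(seed), panel = panel,
      analytes = analytes,
      age_mean = age_mean, age_sd = age_sd, age_min = age_min, age_max = age_max,
      p_female = p_female, female_postmeno_frac = female_postmeno_frac,
      nafld_frac = nafld_frac, year_health_r2 = year_health_r2,
      years = years, year_weights = year_weights,
      p_year_exact = p_year_exact, p_year_range = p_year_range,
      p_year_missing = p_year_missing, range_width = range_width,
      p_health_missing = p_health_missing, p_age_missing = p_age_missing,
      p_bmi_missing = p_bmi_missing,
      instrument = instrument
    ),
    class = "sim_params"
  )
}

#' Default unequal per-year sampling weights (2000--2024)
#'
#' Bimodal over the collection period (an early-2000s cluster and a larger
#' post-2012 cluster, sparse around 2011), so that inverse-sample-size
#' weighting in the trend model is meaningfully exercised. Roughly 38% of
#' the mass sits in 2000--2010.
#'
#' @return Numeric weights, one per year 2000--2024.
#' @export
default_year_weights <- function() {
  c(
    6, 5, 6, 8, 6, 5, 7, 8, 6, 4, 3, # 2000-2010
    1, # 2011
    2, 4, 5, 6, 7, 8, 9, 10, 12, 11, 10, 9, 8 # 2012-2024
  )
}

#' Default instrument/noise settings for the batch generator
#'
#' Response is expressed in isotope-dilution ratio space: the calibration
#' relates native/EIS area ratio to native/EIS amount ratio with slope
#' `cal_slope` and intercept `cal_intercept`. Areas carry multiplicative
#' log-normal noise with coefficient of variation `area_cv`; EIS recovery
#' is truncated-normal; the confirmation channel is a fixed fraction
#' `channel_ratio` of the quantification channel with its own relative
#' noise; retention times jitter around the panel's nominal values, with
#' structurally different internal standards offset by `rt_eis_offset`
#' minutes. Batches of `n_per_batch` specimens each carry procedural
#' blanks, mid-calibration CCVs and native-spiked positive controls.
#'
#' @return Named list of instrument parameters.
#' @export
default_instrument_params <- function() {
  list(
    cal_slope = 1.0, cal_intercept = 0.0,
    cal_levels = c(0.01, 0.05, 0.25, 0.5, 1, 2.5, 5),
    eis_spike = 4, native_spike = 4,
    base_eis_area = 1e5,
    area_cv = 0.05,
    recovery_mean = 0.85, recovery_sd = 0.10,
    channel_ratio = 0.5, channel_ratio_sd = 0.05,
    rt_jitter_sd = 0.02, rt_eis_offset = 0.15,
    ccv_amount_ratio = 0.5,
    sample_mass_mean = 0.5, sample_mass_sd = 0.02,
    blank_mass = 0.5,
    n_per_batch = 20, blanks_per_batch = 4,
    ccv_per_batch = 2, poscontrol_per_batch = 2
  )
}

#' Default per-analyte simulation effects
#'
#' Baselines are anchored to the concentration scale reported for human
#' liver (medians of ~0.03--1.4 ng/g mid-period, PFOS isomers highest);
#' decade slopes are negative for phased-out legacy compounds (strongest
#' for 8:2 FTS and the PFOS isomers), near zero for PFHxS / FOSA /
#' N-MeFOSAA, and slightly positive for the PFOS replacement 9Cl-PF3ONS;
#' age effects are positive for long-chain compounds; sex effects favour
#' males for PFUdA/PFDoA/9Cl-PF3ONS and females for 8:2 FTS; NAFLD lowers
#' the protein/phospholipid-bound compounds. Magnitudes approximate the
#' reported percent-change scale without claiming exact coefficients.
#'
#' @param panel A `pfas_panel`.
#' @return Tibble of per-analyte generator parameters.
#' @export
default_sim_analytes <- function(panel = default_panel()) {
  defaults <- tibble::tribble(
    ~analyte, ~median_ref, ~df_ref, ~beta_year, ~beta_age, ~beta_sex, ~beta_health,
    "PFBA", 0.08, 0.04, -0.10, 0.000, 0.000, 0.000,
    "PFHxA", 0.05, 0.02, -0.10, 0.000, 0.000, 0.000,
    "PFHpA", 0.05, 0.01, -0.10, 0.000, 0.000, 0.000,
    "PFOA", 0.22, 0.62, -0.119, 0.022, 0.000, 0.000,
    "PFNA", 0.18, 0.57, -0.042, 0.028, 0.000, -0.056,
    "PFDA", 0.15, 0.50, -0.021, 0.011, 0.000, 0.000,
    "PFUdA", 0.14, 0.44, -0.028, 0.020, -0.049, -0.086,
    "PFDoA", 0.03, 0.37, -0.002, 0.034, -0.083, -0.119,
    "PFTrDA", 0.10, 0.13, -0.050, 0.010, 0.000, 0.000,
    "PFTeDA", 0.09, 0.01, -0.050, 0.010, 0.000, 0.000,
    "L-PFHxS", 0.10, 0.50, -0.007, 0.018, 0.000, 0.000,
    "Br-PFHxS", 0.05, 0.08, -0.007, 0.018, 0.000, 0.000,
    "PFHpS", 0.15, 0.06, -0.150, 0.010, 0.000, 0.000,
    "L-PFOS", 1.39, 0.99, -0.215, 0.037, 0.000, -0.108,
    "Br-PFOS", 0.89, 0.95, -0.208, 0.053, 0.000, -0.131,
    "PFDS", 0.14, 0.30, -0.187, 0.000, 0.000, 0.000,
    "FOSA", 0.07, 0.28, -0.056, 0.000, 0.000, 0.000,
    "L-N-MeFOSAA", 0.60, 0.52, -0.200, 0.000, 0.000, 0.000,
    "Br-N-MeFOSAA", 0.39, 0.22, -0.051, 0.000, 0.000, 0.000,
    "L-N-EtFOSAA", 0.87, 0.19, -0.086, 0.000, 0.000, 0.000,
    "9Cl-PF3ONS", 0.03, 0.15, 0.029, 0.000, -0.030, -0.036,
    "11Cl-PF3OUdS", 0.02, 0.005, 0.000, 0.000, 0.000, 0.000,
    "3,6-OPFHpA", 0.03, 0.014, 0.000, 0.000, 0.000, 0.000,
    "PFECHS", 0.13, 0.05, -0.050, 0.000, 0.000, 0.000,
    "6:2 FTS", 0.16, 0.09, -0.100, 0.000, 0.000, 0.000,
    "8:2 FTS", 0.17, 0.59, -0.252, 0.027, 0.079, -0.137,
    "10:2 FTS", 1.50, 0.01, -0.100, 0.000, 0.000, 0.000,
    "7:3 FTCA", 0.23, 0.13, -0.050, 0.000, 0.000, 0.000,
    "5:3 FTCA", 0.10, 0.005, -0.050, 0.000, 0.000, 0.000
  )
  df <- defaults[match(panel$name, defaults$analyte), ]
  if (anyNA(df$analyte)) {
    missing <- panel$name[is.na(df$analyte)]
    df$analyte[is.na(df$analyte)] <- missing
    df$median_ref[is.na(df$median_ref)] <- 0.05
    df$df_ref[is.na(df$df_ref)] <- 0.3
    df[is.na(df)] <- 0
  }
  legacy <- df$analyte %in% c(
    "PFBA", "PFHxA", "PFHpA", "PFOA", "PFNA", "PFDA",
    "L-PFOS", "Br-PFOS", "L-N-MeFOSAA"
  )
  sigma <- 0.5
  idl <- 0.02
  blank_ng_mean <- ifelse(legacy, 0.01, 0)
  blank_ng_sd <- ifelse(legacy, 0.005, 0)
  # Typical MDL implied by the blank/IDL model (ng/g at 0.5 g sample mass).
  mdl_anchor <- ifelse(legacy, (blank_ng_mean + 3 * blank_ng_sd) / 0.5, idl)
  # Anchor the mid-period (~2012) log10 centre: frequently detected
  # analytes sit at their reference median; rarely detected ones are
  # placed so that P(conc > typical MDL) matches the reference detection
  # frequency. c0 is the year-2000 baseline under the decade slope.
  mu_mid <- ifelse(
    df$df_ref >= 0.5,
    log10(df$median_ref),
    log10(mdl_anchor) + stats::qnorm(df$df_ref) * sigma
  )
  tibble::tibble(
    analyte = df$analyte,
    log10_c0 = mu_mid - 1.2 * df$beta_year,
    beta_year = df$beta_year,
    beta_age = df$beta_age,
    beta_sex = df$beta_sex,
    beta_health = df$beta_health,
    sigma = sigma,
    idl = idl,
    blank_ng_mean = blank_ng_mean,
    blank_ng_sd = blank_ng_sd
  )
}

# Inverse-CDF sampler for a truncated normal; exact and vectorised.
rtruncnorm_q <- function(n, mean, sd, lo, hi) {
  if (n == 0) {
    return(numeric(0))
  }
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Calibrate logistic NAFLD-by-year model: find (a, b) such that the mean
# prevalence matches `target_frac` and the population squared correlation
# between year and the binary outcome matches `target_r2`, given the
# realized collection years. Var(Y) = E[p(1-p)] + Var(p); Cov(year, Y) =
# Cov(year, p).
calibrate_year_health <- function(years, target_frac, target_r2) {
  x <- years - mean(years)
  vx <- mean(x^2)
  if (target_r2 <= 0 || vx == 0) {
    return(c(a = stats::qlogis(target_frac), b = 0, x_center = mean(years)))
  }
  solve_a <- function(b) {
    stats::uniroot(
      function(a) mean(stats::plogis(a + b * x)) - target_frac,
      interval = c(-200, 200), tol = 1e-10
    )$root
  }
  r2_at <- function(b) {
    a <- solve_a(b)
    p <- stats::plogis(a + b * x)
    cxy <- mean(x * p) - mean(x) * mean(p)
    vy <- mean(p * (1 - p)) + (mean(p^2) - mean(p)^2)
    cxy^2 / (vx * vy)
  }
  b_max <- 5
  if (r2_at(b_max) < target_r2) {
    rlang::abort(
      sprintf(
        "year-health correlation target R^2 = %.2f is infeasible for this year distribution (max attainable %.3f)",
        target_r2, r2_at(b_max)
      ),
      class = "hepapfas_config_error"
    )
  }
  b <- stats::uniroot(function(b) r2_at(b) - target_r2,
    interval = c(0, b_max), tol = 1e-9
  )$root
  c(a = solve_a(b), b = b, x_center = mean(years))
}

#' Generate a synthetic donor cohort
#'
#' Draws `n_donors` donors with the configured demographic structure. Each
#' donor carries *latent* truth columns (`true_age`, `true_year`,
#' `true_health`) that drive concentration generation, alongside the
#' *reported* metadata fields (`age`, `health`, `year_exact`,
#' `year_start`/`year_end`, `bmi`) which emulate real specimen-bank gaps:
#' exact years, date ranges, and missing entries.
#'
#' @param params A [sim_params()] object.
#' @return Tibble of donors.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_donors
  if (n == 0) {
    return(tibble::tibble(
      donor_id = character(), sex = character(), age = numeric(),
      health = character(), year_exact = numeric(), year_start = numeric(),
      year_end = numeric(), bmi = numeric(), true_age = numeric(),
      true_year = numeric(), true_health = character()
    ))
  }
  set.seed(params$seed)
  sex <- ifelse(stats::runif(n) < params$p_female, "female", "male")
  age_true <- numeric(n)
  male <- sex == "male"
  age_true[male] <- rtruncnorm_q(
    sum(male), params$age_mean, params$age_sd, params$age_min, params$age_max
  )
  # Female ages: a postmenopausal-weighted mixture of the same truncated
  # normal, restricted to [46, max] with probability female_postmeno_frac.
  nf <- sum(!male)
  if (nf > 0) {
    post <- stats::runif(nf) < params$female_postmeno_frac
    f_age <- numeric(nf)
    cut <- max(46, params$age_min)
    f_age[post] <- rtruncnorm_q(
      sum(post), params$age_mean, params$age_sd, cut, params$age_max
    )
    f_age[!post] <- rtruncnorm_q(
      sum(!post), params$age_mean, params$age_sd, params$age_min, cut
    )
    age_true[!male] <- f_age
  }
  true_year <- sample(params$years,
    size = n, replace = TRUE,
    prob = params$year_weights / sum(params$year_weights)
  )
  ab <- calibrate_year_health(true_year, params$nafld_frac, params$year_health_r2)
  p_nafld <- stats::plogis(ab[["a"]] + ab[["b"]] * (true_year - ab[["x_center"]]))
  true_health <- ifelse(stats::runif(n) < p_nafld, "NAFLD", "normal")

  date_kind <- sample(c("exact", "range", "missing"),
    size = n, replace = TRUE,
    prob = c(params$p_year_exact, params$p_year_range, params$p_year_missing)
  )
  year_exact <- ifelse(date_kind == "exact", true_year, NA_real_)
  offset <- sample.int(params$range_width + 1, n, replace = TRUE) - 1L
  ys <- pmax(min(params$years), true_year - offset)
  year_start <- ifelse(date_kind == "range", ys, NA_real_)
  year_end <- ifelse(date_kind == "range",
    pmin(max(params$years), ys + params$range_width), NA_real_
  )
  health <- ifelse(stats::runif(n) < params$p_health_missing, NA_character_, true_health)
  age_rep <- ifelse(stats::runif(n) < params$p_age_missing, NA_real_, age_true)
  bmi <- rtruncnorm_q(n, 31.27, 9.17, 16, 80)
  bmi[stats::runif(n) < params$p_bmi_missing] <- NA_real_

  tibble::tibble(
    donor_id = sprintf("D%04d", seq_len(n)),
    sex = sex, age = age_rep, health = health,
    year_exact = year_exact, year_start = year_start, year_end = year_end,
    bmi = bmi,
    true_age = age_true, true_year = as.numeric(true_year), true_health = true_health
  )
}

#' Generate true tissue concentrations
#'
#' For donor *i* and analyte *a*:
#' `log10 C = c0 + b_year (year-2000)/10 + b_age (age-50)/10 +
#'  b_sex 1[female] + b_health 1[NAFLD] + N(0, sigma)`.
#' Uses each donor's latent truth covariates, so donors whose *reported*
#' metadata are ranged or missing still have well-defined concentrations.
#'
#' @param cohort Output of [generate_cohort()].
#' @param params A [sim_params()] object.
#' @return Numeric matrix, donors x analytes (ng/g wet weight), strictly
#'   positive.
#' @export
generate_true_concentrations <- function(cohort, params) {
  stopifnot(inherits(params, "sim_params"), nrow(cohort) >= 1)
  set.seed(params$seed + 1L)
  an <- params$analytes
  n <- nrow(cohort)
  dec_year <- (cohort$true_year - 2000) / 10
  dec_age <- (cohort$true_age - 50) / 10
  female <- as.numeric(cohort$sex == "female")
  nafld <- as.numeric(cohort$true_health == "NAFLD")
  m <- matrix(NA_real_, n, nrow(an), dimnames = list(cohort$donor_id, an$analyte))
  for (j in seq_len(nrow(an))) {
    mu <- an$log10_c0[j] + an$beta_year[j] * dec_year + an$beta_age[j] * dec_age +
      an$beta_sex[j] * female + an$beta_health[j] * nafld
    m[, j] <- 10^(mu + stats::rnorm(n, 0, an$sigma[j]))
  }
  m
}

lognoise <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

#' Generate matrix-matched calibration levels
#'
#' One calibration series per analyte in ratio space (native/EIS amount
#' ratio vs native/EIS area ratio), on the configured true response line
#' with optional relative noise.
#'
#' @param params A [sim_params()] object.
#' @param cal_cv Relative noise on the area ratios (0 = exact line).
#' @return Tibble with columns `analyte`, `amount_ratio`, `area_ratio`,
#'   `idl`.
#' @export
generate_calibration <- function(params, cal_cv = 0) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 2L)
  ins <- params$instrument
  levels <- ins$cal_levels
  out <- tidyr::expand_grid(
    analyte = params$analytes$analyte,
    amount_ratio = levels
  )
  out$area_ratio <- (ins$cal_slope * out$amount_ratio + ins$cal_intercept) *
    lognoise(nrow(out), cal_cv)
  out$idl <- params$analytes$idl[match(out$analyte, params$analytes$analyte)]
  out
}

#' Generate batch-level instrument measurements
#'
#' Converts true concentrations into per-sample x analyte instrument
#' records plus procedural blanks, continuing calibration verification
#' (CCV) standards and positive controls, organised into batches.
#' Quantification-channel areas follow the isotope-dilution response
#' (ratio-space line) times EIS area; EIS areas carry recovery and
#' log-normal noise; the confirmation channel is `channel_ratio` times the
#' quantification channel; specimens and blanks share the same procedural
#' contamination model so that blank correction is meaningful; retention
#' times jitter around the panel's nominal values.
#'
#' @param true_conc Matrix from [generate_true_concentrations()].
#' @param params A [sim_params()] object.
#' @return Tibble of batch measurements (one row per sample x analyte).
#' @export
generate_batches <- function(true_conc, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 3L)
  ins <- params$instrument
  an <- params$analytes
  panel <- params$panel
  n <- nrow(true_conc)
  na_ <- nrow(an)
  donor_ids <- rownames(true_conc)

  n_batches <- max(1L, ceiling(n / ins$n_per_batch))
  batch_of <- rep(seq_len(n_batches), each = ins$n_per_batch)[seq_len(n)]
  mass <- rtruncnorm_q(n, ins$sample_mass_mean, max(ins$sample_mass_sd, 1e-12), 0.1, 1.5)
  if (ins$sample_mass_sd == 0) mass <- rep(ins$sample_mass_mean, n)

  rt_nom <- panel$rt[match(an$analyte, panel$name)]
  eis_off <- ifelse(panel$eis_structure[match(an$analyte, panel$name)] == "different",
    ins$rt_eis_offset, 0
  )

  rows <- function(sample_id, role, batch_id, mass_vec, true_vec, native_spike,
                   with_blank = TRUE) {
    k <- length(sample_id)
    out <- vector("list", na_)
    for (j in seq_len(na_)) {
      blank_ng <- if (with_blank && an$blank_ng_sd[j] > 0) {
        pmax(0, stats::rnorm(k, an$blank_ng_mean[j], an$blank_ng_sd[j]))
      } else if (with_blank) {
        rep(an$blank_ng_mean[j], k)
      } else {
        rep(0, k)
      }
      native_ng <- true_vec[, j] * mass_vec + blank_ng + native_spike
      ratio <- native_ng / ins$eis_spike
      recovery <- pmin(2, pmax(
        0.05,
        stats::rnorm(k, ins$recovery_mean, ins$recovery_sd)
      ))
      if (ins$recovery_sd == 0) recovery <- rep(ins$recovery_mean, k)
      area_eis <- ins$base_eis_area * recovery * lognoise(k, ins$area_cv)
      area_quant <- (ins$cal_slope * ratio + ins$cal_intercept) * area_eis *
        lognoise(k, ins$area_cv)
      area_conf <- area_quant * ins$channel_ratio * lognoise(k, ins$channel_ratio_sd)
      out[[j]] <- tibble::tibble(
        sample_id = sample_id, analyte = an$analyte[j], role = role,
        area_quant = area_quant, area_conf = area_conf, area_eis = area_eis,
        rt_analyte = rt_nom[j] + stats::rnorm(k, 0, ins$rt_jitter_sd),
        rt_eis = rt_nom[j] - eis_off[j] + stats::rnorm(k, 0, ins$rt_jitter_sd),
        sample_mass = mass_vec, eis_spike = ins$eis_spike,
        native_spike = native_spike, batch_id = batch_id
      )
    }
    dplyr::bind_rows(out)
  }

  spec <- rows(donor_ids, "specimen", sprintf("B%02d", batch_of),
    mass, true_conc,
    native_spike = 0
  )

  qc <- vector("list", n_batches)
  zero_mat <- function(k) matrix(0, k, na_)
  for (b in seq_len(n_batches)) {
    bid <- sprintf("B%02d", b)
    nb <- ins$blanks_per_batch
    nc <- ins$ccv_per_batch
    np <- ins$poscontrol_per_batch
    blanks <- rows(sprintf("%s-BLK%d", bid, seq_len(nb)), "blank", bid,
      rep(ins$blank_mass, nb), zero_mat(nb),
      native_spike = 0
    )
    ccv_native <- ins$ccv_amount_ratio * ins$eis_spike
    ccvs <- rows(sprintf("%s-CCV%d", bid, seq_len(nc)), "ccv", bid,
      rep(1, nc), zero_mat(nc),
      native_spike = ccv_native, with_blank = FALSE
    )
    pos <- rows(sprintf("%s-PC%d", bid, seq_len(np)), "positive_control", bid,
      rep(ins$sample_mass_mean, np), zero_mat(np),
      native_spike = ins$native_spike, with_blank = FALSE
    )
    qc[[b]] <- dplyr::bind_rows(blanks, ccvs, pos)
  }
  dplyr::bind_rows(spec, dplyr::bind_rows(qc))
}

#' Generate extractable-organofluorine (EOF) measurements
#'
#' For a subset of donors, simulates combustion-IC fluoride readings in
#' which the true EOF is `eof_excess` times the fluorine-equivalent sum of
#' the targeted panel (the unexplained remainder standing in for
#' non-target organofluorine), plus DI-water procedural blanks and matrix
#' extraction blanks.
#'
#' @param true_conc Matrix from [generate_true_concentrations()].
#' @param params A [sim_params()] object.
#' @param donor_ids Donors to measure (default: the first 8).
#' @param eof_excess True EOF / targeted-fluorine ratio (default 13).
#' @param reading_cv Relative measurement noise.
#' @param di_blank_mean,matrix_blank_mean,matrix_blank_sd Blank levels
#'   (ng F/g).
#' @param dilution_factor Dilution factor applied to the extracts.
#' @return Tibble of EOF measurements (`sample_id`, `fluoride_reading`,
#'   `batch_id`, `dilution_factor`, `role`).
#' @export
generate_eof <- function(true_conc, params,
                         donor_ids = utils::head(rownames(true_conc), 8),
                         eof_excess = 13, reading_cv = 0.1,
                         di_blank_mean = 1.0,
                         matrix_blank_mean = 0.8, matrix_blank_sd = 0.3,
                         dilution_factor = 1) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 4L)
  ffrac <- vapply(params$panel$formula, fluorine_mass_fraction, numeric(1))
  ffrac <- ffrac[match(colnames(true_conc), params$panel$name)]
  targeted_f <- as.numeric(true_conc[donor_ids, , drop = FALSE] %*% ffrac)
  eof_true <- targeted_f * eof_excess
  k <- length(donor_ids)
  spec <- tibble::tibble(
    sample_id = donor_ids,
    fluoride_reading = (eof_true + di_blank_mean) * lognoise(k, reading_cv),
    batch_id = "E01", dilution_factor = dilution_factor, role = "specimen"
  )
  di <- tibble::tibble(
    sample_id = sprintf("E01-DI%d", 1:2),
    fluoride_reading = di_blank_mean * lognoise(2, reading_cv),
    batch_id = "E01", dilution_factor = dilution_factor, role = "di_blank"
  )
  mx <- tibble::tibble(
    sample_id = sprintf("E01-MB%d", 1:2),
    fluoride_reading = pmax(0, stats::rnorm(2, matrix_blank_mean, matrix_blank_sd)),
    batch_id = "E01", dilution_factor = dilution_factor, role = "matrix_blank"
  )
  dplyr::bind_rows(spec, di, mx)
}
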