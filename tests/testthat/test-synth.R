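test_that("generation is deterministic for a fixed seed", {
  p <- sim_params(n_donors = 60, seed = 42)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  t1 <- generate_true_concentrations(c1, p)
  t2 <- generate_true_concentrations(c2, p)
  expect_identical(t1, t2)
  b1 <- generate_batches(t1, p)
  b2 <- generate_batches(t2, p)
  expect_identical(b1, b2)
})

test_that("an empty cohort is empty, not an error", {
  p <- sim_params(n_donors = 0, seed = 1)
  co <- generate_cohort(p)
  expect_equal(nrow(co), 0)
})

test_that("cohort respects demographic bounds and levels", {
  p <- sim_params(n_donors = 300, seed = 3)
  co <- generate_cohort(p)
  expect_true(all(co$true_age >= 18 & co$true_age <= 85))
  expect_true(all(co$sex %in% c("male", "female")))
  expect_true(all(co$true_health %in% c("normal", "NAFLD")))
  expect_true(all(co$true_year %in% 2000:2024))
  expect_true(all(is.na(co$year_exact) | co$year_exact %in% 2000:2024))
  rng <- !is.na(co$year_start)
  expect_true(all(co$year_end[rng] >= co$year_start[rng]))
})

test_that("large-sample age distribution matches its analytic expectation", {
  # Independent oracle: numerical integration of the configured truncated
  # normal (males) and the postmenopausal-weighted two-piece mixture
  # (females).
  p <- sim_params(n_donors = 6000, seed = 11)
  co <- generate_cohort(p)
  tn_mean <- function(lo, hi) {
    z <- stats::integrate(function(x) stats::dnorm(x, p$age_mean, p$age_sd),
      lo, hi
    )$value
    stats::integrate(function(x) x * stats::dnorm(x, p$age_mean, p$age_sd),
      lo, hi
    )$value / z
  }
  exp_male <- tn_mean(18, 85)
  exp_female <- p$female_postmeno_frac * tn_mean(46, 85) +
    (1 - p$female_postmeno_frac) * tn_mean(18, 46)
  expect_lt(abs(mean(co$true_age[co$sex == "male"]) - exp_male), 0.5)
  expect_lt(abs(mean(co$true_age[co$sex == "female"]) - exp_female), 0.5)
  expect_lt(abs(mean(co$sex == "female") - 0.5), 0.03)
  expect_gt(mean(co$true_age[co$sex == "female"] >= 46), 0.82)
})

test_that("NAFLD prevalence and its year correlation hit the targets", {
  p <- sim_params(n_donors = 6000, seed = 5)
  co <- generate_cohort(p)
  expect_lt(abs(mean(co$true_health == "NAFLD") - 0.54), 0.03)
  r2 <- stats::cor(co$true_year, as.numeric(co$true_health == "NAFLD"))^2
  expect_lt(abs(r2 - 0.43), 0.06)
})

test_that("an infeasible year-health correlation target errors", {
  p <- sim_params(n_donors = 50, seed = 1)
  p$year_health_r2 <- 0.99
  expect_error(generate_cohort(p), class = "hepapfas_config_error")
})

test_that("true concentrations follow the log-linear covariate model", {
  cohort <- tibble::tibble(
    donor_id = c("A", "B", "C", "D"),
    sex = c("male", "male", "female", "male"),
    true_age = c(50, 50, 50, 60),
    true_year = c(2000, 2010, 2000, 2000),
    true_health = c("normal", "normal", "normal", "NAFLD")
  )
  p <- sim_params(n_donors = 4, seed = 1)
  p$analytes <- tibble::tibble(
    analyte = "X", log10_c0 = 1, beta_year = -1, beta_age = 0.2,
    beta_sex = 0.3, beta_health = -0.4, sigma = 0, idl = 1e-10,
    blank_ng_mean = 0, blank_ng_sd = 0
  )
  m <- generate_true_concentrations(cohort, p)
  # sigma = 0, no effects for donor A: exactly the baseline
  expect_equal(m["A", "X"], 10^1, tolerance = 1e-12)
  # one decade with beta_year = -1/decade: exactly 10x lower
  expect_equal(m["B", "X"], m["A", "X"] / 10, tolerance = 1e-12)
  # sex and health effects are exact log10 shifts
  expect_equal(log10(m["C", "X"]) - log10(m["A", "X"]), 0.3, tolerance = 1e-12)
  expect_equal(
    log10(m["D", "X"]) - log10(m["A", "X"]),
    0.2 * (60 - 50) / 10 - 0.4,
    tolerance = 1e-12
  )
  expect_true(all(m > 0))
})

test_that("zero-noise batches round-trip through quantification exactly", {
  p <- zero_noise_sim(n_donors = 12, seed = 9, sigma = 0.4)
  co <- generate_cohort(p)
  tc <- generate_true_concentrations(co, p)
  batch <- generate_batches(tc, p)
  cal <- generate_calibration(p)
  q <- quantify_batch(batch, p$panel, cal)
  qc <- q$qc[!q$qc$excluded & !q$qc$censored, ]
  truth <- tc[cbind(qc$sample_id, qc$analyte)]
  expect_true(all(abs(qc$conc - truth) / truth < 1e-10))
})

test_that("zero noise makes every ion abundance ratio exactly zero", {
  p <- zero_noise_sim(n_donors = 6, seed = 2, sigma = 0)
  co <- generate_cohort(p)
  tc <- generate_true_concentrations(co, p)
  batch <- generate_batches(tc, p)
  q <- quantify_batch(batch, p$panel, generate_calibration(p))
  expect_true(all(abs(q$qc$iar) < 1e-12))
})

test_that("no blank contamination means the MDL falls back to the IDL", {
  p <- zero_noise_sim(n_donors = 6, seed = 2, sigma = 0)
  p$analytes$idl <- 0.02
  co <- generate_cohort(p)
  tc <- generate_true_concentrations(co, p)
  q <- quantify_batch(generate_batches(tc, p), p$panel, generate_calibration(p))
  expect_true(all(q$qc$mdl == 0.02))
})

test_that("EOF generator produces specimens and both blank types", {
  p <- sim_params(n_donors = 10, seed = 4)
  co <- generate_cohort(p)
  tc <- generate_true_concentrations(co, p)
  eof <- generate_eof(tc, p)
  expect_setequal(unique(eof$role), c("specimen", "di_blank", "matrix_blank"))
  expect_equal(sum(eof$role == "specimen"), 8)
  expect_true(all(eof$fluoride_reading >= 0))
})
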