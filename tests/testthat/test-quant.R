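test_that("calibration fits recover exact lines and enforce preconditions", {
  x <- c(0.05, 0.25, 0.5, 1, 2, 5)
  ident <- fit_calibration(data.frame(amount_ratio = x, area_ratio = x))
  expect_equal(ident$slope, 1, tolerance = 1e-10)
  expect_equal(ident$intercept, 0, tolerance = 1e-10)
  line <- fit_calibration(data.frame(amount_ratio = x, area_ratio = 2 * x + 0.1))
  expect_equal(line$slope, 2, tolerance = 1e-10)
  expect_equal(line$intercept, 0.1, tolerance = 1e-10)
  expect_error(
    fit_calibration(data.frame(amount_ratio = 1:3, area_ratio = 1:3)),
    class = "hepapfas_calibration_error"
  )
  expect_error(
    fit_calibration(data.frame(amount_ratio = x, area_ratio = -x)),
    class = "hepapfas_calibration_error"
  )
  expect_warning(
    fit_calibration(data.frame(
      amount_ratio = x,
      area_ratio = c(0.1, 0.05, 0.5, 1, 2, 5)
    )),
    "non-monotone"
  )
})

test_that("quantify applies the isotope-dilution back-calculation", {
  curve <- unit_curve()
  # ratio 0.5, 4 ng spike, 0.5 g: 0.5 * 4 / 0.5 = 4 ng/g
  expect_equal(
    quantify(50, 100, curve, eis_spike = 4, sample_mass = 0.5), 4.0,
    tolerance = 1e-12
  )
  expect_equal(quantify(0, 100, curve, sample_mass = 0.5), 0)
  # invariance to common multiplicative loss on both channels
  expect_equal(
    quantify(50, 100, curve, sample_mass = 0.5),
    quantify(25, 50, curve, sample_mass = 0.5)
  )
  expect_warning(
    out <- quantify(c(50, 50), c(100, 0), curve, sample_mass = 0.5),
    "unquantifiable"
  )
  expect_true(is.na(out[2]) && !is.na(out[1]))
})

test_that("MDL follows mean + 3 SD with IDL fallback", {
  expect_equal(compute_mdl(c(0.10, 0.20, 0.30), idl = 0.02),
    0.20 + 3 * stats::sd(c(0.10, 0.20, 0.30)),
    tolerance = 1e-12
  )
  expect_equal(compute_mdl(c(0.10, 0.20, 0.30), idl = 0.02), 0.50,
    tolerance = 1e-12
  )
  expect_equal(compute_mdl(numeric(0), idl = 0.02), 0.02)
  expect_equal(compute_mdl(c(0, 0, 0), idl = 0.02), 0.02)
  expect_warning(one <- compute_mdl(0.3, idl = 0.02), "single blank detect")
  expect_equal(one, 0.02)
  expect_equal(compute_mdl(c(0.2, 0.2, 0.2), idl = 0.02), 0.2)
})

test_that("MDL responds monotonically to blank level and spread", {
  set.seed(101)
  for (i in 1:25) {
    blanks <- stats::runif(5, 0.05, 0.5)
    base <- compute_mdl(blanks, idl = 0.01)
    # a common upward shift moves the MDL by exactly that shift
    shift <- stats::runif(1, 0, 0.5)
    expect_equal(compute_mdl(blanks + shift, idl = 0.01), base + shift,
      tolerance = 1e-10
    )
    # raising the largest blank (mean and SD both increase) never lowers it
    bumped <- blanks
    j <- which.max(blanks)
    bumped[j] <- bumped[j] + stats::runif(1, 0, 0.5)
    expect_gte(compute_mdl(bumped, idl = 0.01) + 1e-12, base)
    # widening the spread around the mean never lowers it
    spread <- mean(blanks) + 1.5 * (blanks - mean(blanks))
    expect_gte(compute_mdl(spread, idl = 0.01) + 1e-12, base)
  }
})

test_that("blank correction gates on the MDL and never goes negative", {
  r <- blank_correct(1.0, blank_mean = 0.2, mdl = 0.5)
  expect_equal(r$conc, 0.8)
  expect_false(r$censored)
  expect_true(r$blank_corrected)
  r2 <- blank_correct(0.4, blank_mean = 0.2, mdl = 0.5)
  expect_true(r2$censored)
  expect_true(is.na(r2$conc))
  r3 <- blank_correct(1.0, blank_mean = 0, mdl = 0.5)
  expect_equal(r3$conc, 1.0)
  expect_false(r3$blank_corrected)
  # subtraction dropping below the MDL censors rather than reporting a tiny
  # or negative value
  r4 <- blank_correct(0.6, blank_mean = 0.55, mdl = 0.5)
  expect_true(r4$censored)
  set.seed(7)
  raw <- stats::runif(50, 0, 2)
  out <- blank_correct(raw, blank_mean = 0.4, mdl = 0.3)
  expect_true(all(is.na(out$conc) | out$conc >= 0))
  expect_true(all(out$censored == is.na(out$conc)))
})

test_that("retention-time windows follow the 0.1 / 0.4 min rules", {
  expect_true(rt_check(5.05, 5.00, same_structure = TRUE))
  expect_false(rt_check(5.15, 5.00, same_structure = TRUE))
  # different structure: compare against the CCV shift
  expect_true(rt_check(5.55, 5.00, same_structure = FALSE, ccv_shift = 0.20))
  expect_false(rt_check(5.70, 5.00, same_structure = FALSE, ccv_shift = 0.20))
  expect_warning(
    bad <- rt_check(5.1, 5.0, same_structure = FALSE, ccv_shift = NA),
    "CCV"
  )
  expect_false(bad)
})

test_that("ion abundance ratio is CCV-normalized, offset by one, bounded", {
  # sample ratio equal to CCV mean: zero deviation
  r <- ion_abundance_ratio(50, 100, ccv_conf = c(50, 50), ccv_quant = c(100, 100))
  expect_equal(r$iar, 0)
  expect_true(r$iar_ok)
  # sample ratio 1.2 vs CCV mean 0.5: 1.2/0.5 - 1 = 1.4, fails
  r2 <- ion_abundance_ratio(120, 100, ccv_conf = 50, ccv_quant = 100)
  expect_equal(r2$iar, 1.4, tolerance = 1e-12)
  expect_false(r2$iar_ok)
  # zero confirmation area: iar = -1, boundary passes
  r3 <- ion_abundance_ratio(0, 100, ccv_conf = 50, ccv_quant = 100)
  expect_equal(r3$iar, -1)
  expect_true(r3$iar_ok)
  # zero quantification area: undefined, fails
  r4 <- ion_abundance_ratio(10, 0, ccv_conf = 50, ccv_quant = 100)
  expect_false(r4$iar_ok)
  expect_error(
    ion_abundance_ratio(10, 10, ccv_conf = numeric(0), ccv_quant = numeric(0)),
    class = "hepapfas_qc_error"
  )
  expect_error(
    ion_abundance_ratio(10, 10, ccv_conf = 0, ccv_quant = 0),
    class = "hepapfas_qc_error"
  )
})

test_that("CCVs scored against their own mean average to zero", {
  set.seed(12)
  ccv_quant <- stats::runif(6, 50, 150)
  ccv_conf <- ccv_quant * stats::runif(6, 0.4, 0.6)
  r <- ion_abundance_ratio(ccv_conf, ccv_quant, ccv_conf, ccv_quant)
  expect_lt(abs(mean(r$iar)), 1e-12)
})

test_that("EIS recovery limits are inclusive", {
  expect_true(eis_recovery_check(100, 100)$recovery_ok)
  expect_false(eis_recovery_check(10, 100)$recovery_ok)
  expect_true(eis_recovery_check(150, 100)$recovery_ok) # upper boundary
  expect_true(eis_recovery_check(20, 100)$recovery_ok) # lower boundary
  expect_false(eis_recovery_check(151, 100)$recovery_ok)
})

test_that("exclusion logic works per record and per sample, order-invariant", {
  qc <- tibble::tibble(
    sample_id = rep(c("S1", "S2"), each = 4),
    analyte = rep(letters[1:4], 2),
    rt_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
    iar_ok = TRUE,
    recovery_ok = TRUE,
    detected = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  out <- apply_exclusions(qc, sample_fail_fraction_threshold = 0.75)
  # S1 is clean
  expect_true(all(!out$excluded[out$sample_id == "S1"]))
  # S2: 4/4 failed-or-ND > 0.75, whole sample excluded
  expect_true(all(out$sample_excluded[out$sample_id == "S2"]))

  # single failing record in an otherwise passing sample drops only itself
  qc2 <- qc
  qc2$rt_ok <- c(FALSE, rep(TRUE, 7))
  qc2$detected <- TRUE
  out2 <- apply_exclusions(qc2, 0.75)
  expect_equal(sum(out2$excluded), 1)
  expect_false(any(out2$sample_excluded))

  # threshold is strict: exactly 75% failing does not exclude the sample,
  # 78% (as a fraction above 0.75) does
  qc3 <- tibble::tibble(
    sample_id = "S3", analyte = sprintf("a%02d", 1:50),
    rt_ok = c(rep(FALSE, 39), rep(TRUE, 11)),
    iar_ok = TRUE, recovery_ok = TRUE, detected = TRUE
  )
  out3 <- apply_exclusions(qc3, 0.75) # 39/50 = 78%
  expect_true(all(out3$sample_excluded))

  # order invariance
  set.seed(3)
  perm <- sample(nrow(qc))
  outp <- apply_exclusions(qc[perm, ], 0.75)
  key <- paste(out$sample_id, out$analyte)
  keyp <- paste(outp$sample_id, outp$analyte)
  expect_equal(outp$excluded[order(keyp)], out$excluded[order(key)])
})
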