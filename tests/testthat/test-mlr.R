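test_that("analyte selection applies the detection threshold and appends the sum", {
  donors <- tibble::tibble(
    donor_id = sprintf("D%03d", 1:60), age = 50, sex = "male",
    health = "normal", year = 2010
  )
  cens <- c(rep(FALSE, 30), rep(TRUE, 30), rep(FALSE, 29), rep(TRUE, 31))
  tb <- toy_cohort(donors, c("hit30", "hit29"), conc = 1, censored = cens)
  expect_equal(select_analytes(tb, min_detects = 30), c("hit30", "sum"))
  expect_setequal(select_analytes(tb, min_detects = 0), c("hit30", "hit29", "sum"))
})

test_that("the percent-change transform matches its closed form exactly", {
  expect_equal(beta_to_percent_change(0, "continuous"), 0)
  expect_equal(beta_to_percent_change(0, "binary"), 0)
  # beta_year = -0.025/yr: (10^-0.25 - 1) * 100
  expect_equal(
    beta_to_percent_change(-0.025, "continuous"),
    (10^-0.25 - 1) * 100,
    tolerance = 1e-10
  )
  expect_equal(beta_to_percent_change(-0.025, "continuous"), -43.77,
    tolerance = 1e-4
  )
  # beta_sex = +0.0792: 10^0.0792 = 1.20
  expect_equal(
    beta_to_percent_change(0.0792, "binary"),
    (10^0.0792 - 1) * 100,
    tolerance = 1e-10
  )
  expect_equal(beta_to_percent_change(0.0792, "binary"), 20.0, tolerance = 1e-2)
  # sign preservation
  b <- seq(-0.4, 0.4, by = 0.05)
  expect_true(all(sign(beta_to_percent_change(b, "continuous")) == sign(b)))
})

test_that("percent-change transform is a bijection on each branch", {
  b <- c(-0.3, -0.113, -0.025, 0, 0.0079, 0.0792, 0.2)
  for (kind in c("continuous", "binary")) {
    round_trip <- percent_change_to_beta(beta_to_percent_change(b, kind), kind)
    expect_equal(round_trip, b, tolerance = 1e-10)
    pc <- c(-44, -23, 0, 7, 20)
    expect_equal(
      beta_to_percent_change(percent_change_to_beta(pc, kind), kind), pc,
      tolerance = 1e-10
    )
  }
})

test_that("VIF follows 1/(1 - R2) with closed-form checks", {
  # orthogonal predictors
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(x)), c(1, 1))
  # two predictors: VIF = 1/(1 - cor^2)
  set.seed(31)
  x1 <- stats::rnorm(50)
  x2 <- 0.7 * x1 + stats::rnorm(50, 0, 0.5)
  v <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(v), rep(1 / (1 - stats::cor(x1, x2)^2), 2), tolerance = 1e-10)
  # the R2 = 0.43 arithmetic: 1/(1 - 0.43)
  expect_equal(1 / (1 - 0.43), 1.754, tolerance = 1e-3)
  # perfect collinearity
  expect_true(all(is.infinite(vif(cbind(x1, 2 * x1)))))
  # affine invariance
  v2 <- vif(cbind(x1 = 3 * x1 + 5, x2 = -2 * x2 + 1))
  expect_equal(unname(v2), unname(v), tolerance = 1e-9)
  expect_true(all(vif(cbind(x1, x2, x3 = stats::rnorm(50))) >= 1))
  expect_error(vif(cbind(x1)), class = "hepapfas_mlr_error")
})

test_that("MLR coefficients equal the normal-equation solution", {
  set.seed(32)
  n <- 40
  donors <- tibble::tibble(
    donor_id = sprintf("D%03d", 1:n),
    age = stats::runif(n, 20, 80),
    sex = sample(c("male", "female"), n, replace = TRUE),
    health = sample(c("normal", "NAFLD"), n, replace = TRUE),
    year = sample(2000:2024, n, replace = TRUE)
  )
  conc <- 10^stats::rnorm(n, 0, 0.5)
  tb <- toy_cohort(donors, "X", conc = conc)
  fit <- fit_mlr(tb, "X")
  X <- cbind(
    1, donors$year, donors$age,
    as.numeric(donors$sex == "female"), as.numeric(donors$health == "NAFLD")
  )
  beta_hat <- solve(crossprod(X), crossprod(X, log10(conc)))
  expect_equal(fit$coefficients$beta, beta_hat[-1], tolerance = 1e-8)
  expect_equal(fit$n_obs, n)
  expect_true(all(fit$vif >= 1))
})

test_that("rank-deficient designs error naming the collinear column", {
  donors <- tibble::tibble(
    donor_id = sprintf("D%03d", 1:30),
    age = stats::runif(30, 20, 80),
    sex = "male", # constant column -> collinear with intercept
    health = sample(c("normal", "NAFLD"), 30, replace = TRUE),
    year = sample(2000:2024, 30, replace = TRUE)
  )
  tb <- toy_cohort(donors, "X", conc = 1)
  expect_error(fit_mlr(tb, "X"), "sex_female", class = "hepapfas_mlr_error")
})

test_that("MLR on the summed response uses MDL/2-substituted sums", {
  set.seed(33)
  n <- 50
  donors <- tibble::tibble(
    donor_id = sprintf("D%03d", 1:n),
    age = stats::runif(n, 20, 80),
    sex = sample(c("male", "female"), n, replace = TRUE),
    health = sample(c("normal", "NAFLD"), n, replace = TRUE),
    year = sample(2000:2024, n, replace = TRUE)
  )
  cens <- as.logical(stats::rbinom(2 * n, 1, 0.3))
  tb <- toy_cohort(donors, c("a", "b"),
    conc = 10^stats::rnorm(2 * n, 0, 0.4),
    censored = cens, mdl = 0.1
  )
  fit <- fit_mlr(tb, "sum")
  sums <- sum_pfas(tb, "substituted")
  X <- cbind(
    1, sums$year, sums$age,
    as.numeric(sums$sex == "female"), as.numeric(sums$health == "NAFLD")
  )
  beta_hat <- solve(crossprod(X), crossprod(X, log10(sums$sum_pfas)))
  expect_equal(fit$coefficients$beta, beta_hat[-1], tolerance = 1e-8)
})

test_that("D'Agostino-Pearson omnibus matches independent reference values", {
  # Reference statistics/p-values computed with an independent
  # implementation of the K2 omnibus test (scipy.stats.normaltest) and
  # frozen here.
  x1 <- c(
    -1.3, 0.2, 0.5, 1.7, -0.6, 0.3, -2.1, 0.8, 1.1, -0.4,
    0.0, 2.2, -1.8, 0.9, 0.6, -0.2, 1.4, -0.7, 0.1, 0.5
  )
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 0.527165312396, tolerance = 1e-9)
  expect_equal(r1$p.value, 0.768294115544, tolerance = 1e-9)
  x2 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 0.9, 1.2, 1.6, 2.2, 3.1, 4.5, 6.3, 9.0, 12.5)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 10.383779504336, tolerance = 1e-9)
  expect_equal(r2$p.value, 0.005561487046, tolerance = 1e-9)
})

test_that("residual normality reports three tests with small-n rules", {
  set.seed(34)
  p <- residual_normality(stats::rnorm(205))
  expect_named(p, c("shapiro_wilk", "dagostino_pearson", "kolmogorov_smirnov"))
  expect_true(all(p > 0 & p <= 1))
  small <- residual_normality(c(0.1, -0.2, 0.3, -0.1, 0.05))
  expect_false(is.na(small[["shapiro_wilk"]]))
  expect_true(is.na(small[["dagostino_pearson"]]))
  expect_error(dagostino_pearson(1:5), class = "hepapfas_mlr_error")
})
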