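# Multivariate covariate models: log10 concentration on sampling year,
# age, sex and liver-health status, fitted by OLS on complete-case rows
# with nondetects substituted at MDL/2. Coefficients are reported both in
# log10 units and as percent changes — per decade for the continuous
# predictors (year, age), per category for the binary ones (female vs
# male, NAFLD vs healthy).

#' Select analytes for covariate modeling
#'
#' Analytes detected in at least `min_detects` donors (default 30, chosen
#' for reliable parametric estimates while retaining heterogeneous
#' detection patterns); the summed-PFAS pseudo-analyte `"sum"` is always
#' appended.
#'
#' @param table A `pfas_cohort`.
#' @param min_detects Minimum number of detects.
#' @return Character vector of analyte names plus `"sum"`.
#' @export
select_analytes <- function(table, min_detects = 30) {
  df <- detection_frequency(table)
  c(df$analyte[df$n_detects >= min_detects], "sum")
}

#' Percent-change transform of a log10-scale coefficient
#'
#' `(10^beta - 1) * 100`, with continuous predictors (year, age; beta in
#' log10 units per year) first scaled by 10 so the change reads per
#' decade. The sign of the output always equals the sign of beta; the
#' transform is a bijection on each branch ([percent_change_to_beta()] is
#' its exact inverse).
#'
#' @param beta Coefficient(s), log10 units (per year for continuous
#'   predictors, per category for binary ones).
#' @param predictor_kind `"continuous"` or `"binary"`.
#' @return Percent change(s).
#' @export
beta_to_percent_change <- function(beta, predictor_kind = c("continuous", "binary")) {
  predictor_kind <- match.arg(predictor_kind)
  scaled <- if (predictor_kind == "continuous") 10 * beta else beta
  (10^scaled - 1) * 100
}

#' @rdname beta_to_percent_change
#' @param percent Percent change(s) to invert back to a coefficient.
#' @export
percent_change_to_beta <- function(percent, predictor_kind = c("continuous", "binary")) {
  predictor_kind <- match.arg(predictor_kind)
  scaled <- log10(percent / 100 + 1)
  if (predictor_kind == "continuous") scaled / 10 else scaled
}

#' Variance inflation factors
#'
#' For each predictor column, `1/(1 - R^2)` from regressing it on the
#' remaining predictors (with intercept). Perfect collinearity yields
#' `Inf`. VIFs are >= 1 and invariant under affine rescaling of the
#' predictors.
#'
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column), >= 2 columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  if (ncol(x) < 2) {
    rlang::abort("VIF needs >= 2 predictors", class = "hepapfas_mlr_error")
  }
  vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    res <- fit$residuals
    tot <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - sum(res^2) / tot
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(x))
}

#' Residual normality diagnostics
#'
#' Three tests reported side by side, diagnostics only (no automatic
#' action): Shapiro--Wilk (`stats::shapiro.test`), the D'Agostino--Pearson
#' K\eqn{^2} omnibus (skewness and kurtosis Z statistics combined,
#' chi-squared with 2 df; requires n >= 8), and Kolmogorov--Smirnov on
#' standardized residuals against the standard normal. Tests whose sample
#' size requirements are not met are reported as `NA`.
#'
#' @param residuals Numeric residual vector.
#' @return Named numeric vector of p-values: `shapiro_wilk`,
#'   `dagostino_pearson`, `kolmogorov_smirnov`.
#' @export
residual_normality <- function(residuals) {
  r <- residuals[!is.na(residuals)]
  n <- length(r)
  sw <- if (n >= 3 && n <= 5000) stats::shapiro.test(r)$p.value else NA_real_
  dp <- if (n >= 8) dagostino_pearson(r)$p.value else NA_real_
  ks <- if (n >= 3 && stats::sd(r) > 0) {
    suppressWarnings(
      stats::ks.test((r - mean(r)) / stats::sd(r), "pnorm")$p.value
    )
  } else {
    NA_real_
  }
  c(shapiro_wilk = sw, dagostino_pearson = dp, kolmogorov_smirnov = ks)
}

#' D'Agostino--Pearson omnibus normality test
#'
#' The classical K\eqn{^2} statistic: the sum of squared normalized
#' skewness (D'Agostino 1970) and kurtosis (Anscombe--Glynn 1983) Z
#' statistics, referred to a chi-squared distribution with 2 degrees of
#' freedom. Requires n >= 8.
#'
#' @param x Numeric vector.
#' @return List with `statistic` (K2), `z_skew`, `z_kurt`, `p.value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) {
    rlang::abort("D'Agostino-Pearson test requires n >= 8",
      class = "hepapfas_mlr_error"
    )
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # Skewness Z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # Kurtosis Z (Anscombe & Glynn 1983)
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (g2 - eg2) / sqrt(vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
    ((1 - 2 / a) / (1 + xs * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(
    statistic = k2, z_skew = z1, z_kurt = z2,
    p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE)
  )
}

#' Fit the multivariate covariate model for one analyte
#'
#' OLS of log10 concentration on sampling year, age, sex (male = 0,
#' female = 1) and liver health (normal = 0, NAFLD = 1), entered
#' simultaneously, on complete-case rows only. Nondetects are substituted
#' at MDL/2 before the log transform. For `analyte = "sum"` the response
#' is the MDL/2-substituted summed PFAS. Returns the coefficient table
#' with percent changes (per decade for year and age), the overall F-test,
#' VIFs and residual-normality diagnostics.
#'
#' @param table A `pfas_cohort`.
#' @param analyte Analyte name, or `"sum"`.
#' @return An `mlr_fit` list: `analyte`, `coefficients` tibble
#'   (`predictor`, `beta`, `se`, `p_value`, `percent_change`,
#'   `significant`), `r2`, `f_p_value`, `vif`, `normality`, `n_obs`,
#'   `residuals`.
#' @export
fit_mlr <- function(table, analyte) {
  tb <- tibble::as_tibble(table)
  if (identical(analyte, "sum")) {
    d <- sum_pfas(tb, mode = "substituted")
    d$value <- d$sum_pfas
  } else {
    d <- substitute_nondetects(tb[tb$analyte == analyte, ])
    if (nrow(d) == 0) {
      rlang::abort(sprintf("analyte '%s' not found in cohort", analyte),
        class = "hepapfas_mlr_error"
      )
    }
  }
  d <- d[stats::complete.cases(d[, c("value", "year", "age", "sex", "health")]) &
    d$value > 0, ]
  if (nrow(d) < 10) {
    rlang::abort(sprintf("too few complete cases for analyte '%s'", analyte),
      class = "hepapfas_mlr_error"
    )
  }
  x <- cbind(
    year = d$year,
    age = d$age,
    sex_female = as.numeric(d$sex == "female"),
    health_nafld = as.numeric(d$health == "NAFLD")
  )
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    piv <- qrx$pivot[(qrx$rank + 1):(ncol(x) + 1)] - 1
    rlang::abort(
      sprintf(
        "rank-deficient design: collinear column(s) %s",
        paste(colnames(x)[piv[piv > 0]], collapse = ", ")
      ),
      class = "hepapfas_mlr_error"
    )
  }
  df_fit <- data.frame(log10_conc = log10(d$value), x)
  fit <- stats::lm(log10_conc ~ year + age + sex_female + health_nafld,
    data = df_fit
  )
  sm <- summary(fit)
  co <- sm$coefficients[-1, , drop = FALSE]
  kind <- c(year = "continuous", age = "continuous",
    sex_female = "binary", health_nafld = "binary")
  coefs <- tibble::tibble(
    predictor = rownames(co),
    beta = unname(co[, 1]), se = unname(co[, 2]), p_value = unname(co[, 4]),
    percent_change = vapply(
      seq_len(nrow(co)),
      function(i) beta_to_percent_change(co[i, 1], kind[[rownames(co)[i]]]),
      numeric(1)
    ),
    significant = co[, 4] < 0.05
  )
  fstat <- sm$fstatistic
  structure(
    list(
      analyte = analyte,
      coefficients = coefs,
      r2 = sm$r.squared,
      f_p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
      vif = vif(x),
      normality = residual_normality(stats::resid(fit)),
      n_obs = nrow(d),
      residuals = unname(stats::resid(fit))
    ),
    class = "mlr_fit"
  )
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf(
    "Covariate model for %s (n = %d, R2 = %.3f, F-test p = %.3g)\n",
    x$analyte, x$n_obs, x$r2, x$f_p_value
  ))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Fit covariate models for all qualifying analytes
#'
#' Runs [fit_mlr()] for every analyte selected by [select_analytes()]
#' (detects >= `min_detects`, plus the summed PFAS).
#'
#' @param table A `pfas_cohort`.
#' @param min_detects Detection threshold for inclusion.
#' @return Named list of `mlr_fit` objects.
#' @export
fit_all_mlr <- function(table, min_detects = 30) {
  analytes <- select_analytes(table, min_detects)
  fits <- lapply(analytes, function(a) {
    tryCatch(fit_mlr(table, a), hepapfas_mlr_error = function(e) NULL)
  })
  stats::setNames(fits, analytes)[!vapply(fits, is.null, logical(1))]
}
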