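# Inverse-sample-size-weighted log-linear temporal trends. Each
# observation is weighted by 1/(number of observations in its collection
# year), so years with many specimens do not dominate the regression. The
# model is log10(concentration) = beta0 + beta1 * year; geometric means
# and percent reductions are derived from the fitted line.

#' Fit the inverse-sample-size-weighted temporal trend
#'
#' Weighted least squares of `log10(value)` on year with weights
#' `1/n_year` (shared by every observation from the same year), solved in
#' closed form on a year axis centred at the weighted mean year for
#' numerical conditioning (the reported coefficients are on the original
#' year scale). Standard errors come from the weighted residual variance
#' with n - 2 degrees of freedom; the slope p-value is a two-sided t-test.
#'
#' @param values Concentrations (ng/g), strictly positive.
#' @param years Resolved collection years (same length).
#' @return A `trend_fit` list: `beta0`, `beta1` (log10 units/year), `se0`,
#'   `se1`, `p_value` (for `beta1`), `r2` (weighted), `n_obs`, `df`,
#'   `weights`, `years`, `log10_values`.
#' @export
fit_weighted_trend <- function(values, years) {
  keep <- !is.na(values) & !is.na(years)
  values <- values[keep]
  years <- years[keep]
  if (length(values) < 3 || length(unique(years)) < 2) {
    rlang::abort(
      "need >= 3 observations spanning >= 2 distinct years to fit a trend",
      class = "hepapfas_trend_error"
    )
  }
  if (any(values <= 0)) {
    rlang::abort(
      "non-positive concentration in trend input; use a sum mode that yields positive values or drop all-ND donors",
      class = "hepapfas_trend_error"
    )
  }
  y <- log10(values)
  n_year <- table(years)
  w <- as.numeric(1 / n_year[as.character(years)])
  sw <- sum(w)
  xbar <- sum(w * years) / sw
  ybar <- sum(w * y) / sw
  xc <- years - xbar
  sxx <- sum(w * xc^2)
  sxy <- sum(w * xc * (y - ybar))
  beta1 <- sxy / sxx
  beta0 <- ybar - beta1 * xbar
  resid <- y - (beta0 + beta1 * years)
  n <- length(y)
  df <- n - 2
  s2 <- sum(w * resid^2) / df
  se1 <- sqrt(s2 / sxx)
  se0 <- sqrt(s2 * (1 / sw + xbar^2 / sxx))
  if (s2 <= 0) {
    # Perfect fit: a zero slope on constant data is "no trend" (p = 1); a
    # nonzero slope on an exact line is unambiguous (p = 0).
    p <- if (beta1 == 0) 1 else 0
  } else {
    tval <- beta1 / se1
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  }
  ss_tot <- sum(w * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - sum(w * resid^2) / ss_tot else NA_real_
  structure(
    list(
      beta0 = beta0, beta1 = beta1, se0 = se0, se1 = se1,
      p_value = p, r2 = r2, n_obs = n, df = df,
      weights = w, years = years, log10_values = y
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "Weighted log-linear trend (n = %d, %d years)\n  slope: %.4f log10/yr (%.1f%% per decade), SE %.4f, p = %.3g\n  weighted R2 = %.3f\n",
    x$n_obs, length(unique(x$years)), x$beta1,
    (10^(10 * x$beta1) - 1) * 100, x$se1, x$p_value, x$r2
  ))
  invisible(x)
}

#' Build a trend line from two fitted geometric-mean endpoints
#'
#' Utility for working with a published fitted line reported only through
#' its geometric means at the period endpoints: recovers the implied
#' log-linear slope and intercept.
#'
#' @param gm_start,gm_end Geometric means (ng/g) at `year_start` /
#'   `year_end`.
#' @param year_start,year_end Endpoint years.
#' @return A minimal `trend_fit` (coefficients only).
#' @export
trend_from_endpoints <- function(gm_start, year_start, gm_end, year_end) {
  stopifnot(gm_start > 0, gm_end > 0, year_end > year_start)
  beta1 <- (log10(gm_end) - log10(gm_start)) / (year_end - year_start)
  beta0 <- log10(gm_start) - beta1 * year_start
  structure(
    list(
      beta0 = beta0, beta1 = beta1, se0 = NA_real_, se1 = NA_real_,
      p_value = NA_real_, r2 = NA_real_, n_obs = 2L, df = 0L,
      weights = NULL, years = c(year_start, year_end),
      log10_values = log10(c(gm_start, gm_end))
    ),
    class = "trend_fit"
  )
}

#' Modeled geometric mean at a year
#'
#' `10^(beta0 + beta1 * year)` from a fitted trend.
#'
#' @param fit A `trend_fit`.
#' @param year Year(s).
#' @return Geometric mean concentration(s), ng/g.
#' @export
geometric_mean_at <- function(fit, year) {
  stopifnot(inherits(fit, "trend_fit"))
  10^(fit$beta0 + fit$beta1 * year)
}

#' Percent reduction between two years on the fitted trend
#'
#' `100 * (1 - GM(year_end)/GM(year_start)) =
#'  100 * (1 - 10^(beta1 * (year_end - year_start)))`; invariant to any
#' common rescaling of the concentrations.
#'
#' @param fit A `trend_fit`.
#' @param year_start,year_end Period endpoints (`year_end > year_start`).
#' @return Percent reduction (positive for a decline).
#' @export
percent_reduction <- function(fit, year_start, year_end) {
  stopifnot(inherits(fit, "trend_fit"), year_end > year_start)
  100 * (1 - 10^(fit$beta1 * (year_end - year_start)))
}

#' Per-analyte weighted trends with significance labels
#'
#' Fits [fit_weighted_trend()] for each analyte with at least
#' `min_years` distinct collection years of usable values (detected
#' concentrations by default, or MDL/2-substituted values), and labels the
#' direction at the chosen significance level. Analytes with insufficient
#' data are skipped and listed in the `skipped` attribute.
#'
#' @param table A `pfas_cohort`.
#' @param mode `"detected_only"` (per-analyte detected concentrations) or
#'   `"substituted"` (MDL/2 filled).
#' @param alpha Significance level for the trend label.
#' @param min_years Minimum distinct years required.
#' @return Tibble with one row per fitted analyte: `analyte`, `beta0`,
#'   `beta1`, `se1`, `p_value`, `r2`, `n_obs`, `label`
#'   (decline / no-change / increase).
#' @export
per_analyte_trends <- function(table, mode = c("detected_only", "substituted"),
                               alpha = 0.05, min_years = 3) {
  mode <- match.arg(mode)
  tb <- tibble::as_tibble(table)
  tb <- tb[!is.na(tb$year), ]
  if (mode == "substituted") {
    tb <- substitute_nondetects(tb)
  } else {
    tb <- tb[!tb$censored, ]
    tb$value <- tb$conc
  }
  analytes_all <- unique(tibble::as_tibble(table)$analyte)
  out <- lapply(split(tb, tb$analyte), function(d) {
    if (length(unique(d$year)) < min_years || sum(d$value > 0) < min_years) {
      return(NULL)
    }
    fit <- fit_weighted_trend(d$value, d$year)
    tibble::tibble(
      analyte = d$analyte[1], beta0 = fit$beta0, beta1 = fit$beta1,
      se1 = fit$se1, p_value = fit$p_value, r2 = fit$r2, n_obs = fit$n_obs,
      label = if (fit$p_value < alpha) {
        if (fit$beta1 < 0) "decline" else "increase"
      } else {
        "no-change"
      }
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "skipped") <- setdiff(analytes_all, res$analyte)
  res
}
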