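# Linear trend estimation for annual series: per-grid concentration trends
# and aggregate exposure-metric trends, with classical OLS t-tests.

#' Fit a linear trend to an annual series
#'
#' Ordinary least squares of the annual values on calendar year, with the
#' two-sided t-test on the slope. Slopes are reported both per year and per
#' decade (10x). A trend with p < 0.05 is conventionally called
#' statistically significant.
#'
#' @param years Numeric calendar years.
#' @param values Annual values; pairs with missing values are dropped.
#' @return Object of class `trend_fit`: `slope_per_year`,
#'   `slope_per_decade`, `intercept`, `se`, `p_value`, `ci95` (slope per
#'   year), `n`.
#' @export
fit_trend <- function(years, values) {
  ok <- !is.na(years) & !is.na(values)
  years <- years[ok]; values <- values[ok]
  if (length(values) < 3) stop("insufficient data: need >= 3 annual values")
  if (stats::var(years) == 0) stop("contract error: zero variance in year")
  fit <- stats::lm(values ~ years)
  # exact linear series are legitimate input; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["years", "Estimate"]
  se <- sm["years", "Std. Error"]
  p <- sm["years", "Pr(>|t|)"]
  ci <- slope + c(-1, 1) * stats::qt(0.975, length(values) - 2) * se
  structure(list(slope_per_year = slope, slope_per_decade = 10 * slope,
                 intercept = unname(stats::coef(fit)[1]), se = se,
                 p_value = p, ci95 = ci, n = length(values)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend: %+.4g per year (%+.4g per decade), p = %.3g, n = %d\n",
              x$slope_per_year, x$slope_per_decade, x$p_value, x$n))
  invisible(x)
}

#' Calendar-year mean fields from a daily field
#'
#' A cell-year needs at least `min_frac` of its days present, else `NA`.
#'
#' @param field A [daily_field()].
#' @param min_frac Completeness requirement (default 0.75).
#' @return List: `years` (integer vector), `values` array
#'   `(year, lat, lon)`.
#' @export
annual_means <- function(field, min_frac = 0.75) {
  yrs <- as.integer(format(field$dates, "%Y"))
  uy <- sort(unique(yrs))
  g <- field$grid
  out <- array(NA_real_, c(length(uy), g$nlat, g$nlon))
  for (yi in seq_along(uy)) {
    sel <- which(yrs == uy[yi])
    need <- ceiling(length(sel) * min_frac)
    block <- field$values[sel, , , drop = FALSE]
    out[yi, , ] <- apply(block, c(2, 3), function(v) {
      v <- v[!is.na(v)]
      if (length(v) < need) NA_real_ else mean(v)
    })
  }
  list(years = uy, values = out)
}

#' Per-grid linear trends of annual values
#'
#' Fits the [fit_trend()] regression cell-wise with vectorized closed-form
#' OLS (identical to `lm` up to numerical round-off). Cells with fewer than
#' `min_years` non-missing annual values are `NA`.
#'
#' @param annual A list as from [annual_means()] (`years`, `values`).
#' @param min_years Minimum years per cell (default 3).
#' @return List of matrices: `slope` (per year), `slope_per_decade`, `p`.
#' @export
grid_trends <- function(annual, min_years = 3) {
  yrs <- annual$years
  dims <- dim(annual$values)
  ny <- dims[1]; nlat <- dims[2]; nlon <- dims[3]
  vmat <- matrix(annual$values, ny, nlat * nlon)  # years x cells
  slope <- pv <- rep(NA_real_, nlat * nlon)
  for (c in seq_len(nlat * nlon)) {
    y <- vmat[, c]
    ok <- !is.na(y)
    n <- sum(ok)
    if (n < min_years) next
    x <- yrs[ok]; y <- y[ok]
    xm <- mean(x); ym <- mean(y)
    sxx <- sum((x - xm)^2)
    b <- sum((x - xm) * (y - ym)) / sxx
    res <- y - ym - b * (x - xm)
    if (n > 2) {
      s2 <- sum(res^2) / (n - 2)
      tstat <- b / sqrt(s2 / sxx)
      pv[c] <- if (s2 == 0) 0 else 2 * stats::pt(-abs(tstat), n - 2)
    }
    slope[c] <- b
  }
  list(slope = matrix(slope, nlat, nlon),
       slope_per_decade = matrix(10 * slope, nlat, nlon),
       p = matrix(pv, nlat, nlon))
}
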