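# Covariate and unit derivations: ozone unit conversion, relative humidity,
# daily max 8-h ozone, and local-time daily aggregation of hourly fields.

# ideal-gas conversion constants for ozone at the reference state used to
# unify station units: 25.5 degC (298.65 K) and 101.325 kPa
.MW_O3 <- 48.00        # g/mol
.R_GAS <- 8.314462618  # J/(mol K)
.T_REF <- 298.65       # K
.P_REF <- 101.325      # kPa

#' Convert ozone mixing ratio (ppb) to mass concentration (ug/m3)
#'
#' Uses the ideal gas law at 25.5 degC and 101.325 kPa, under which
#' 1 ppb of ozone is approximately 1.96 ug/m3. The conversion is linear.
#'
#' @param value_ppb Mixing ratio in parts per billion; finite, vectorized.
#' @return Concentration in ug/m3.
#' @examples
#' round(ppb_to_ugm3(1), 2)  # 1.96
#' @export
ppb_to_ugm3 <- function(value_ppb) {
  value_ppb * (.MW_O3 * .P_REF) / (.R_GAS * .T_REF)
}

#' Daily mean relative humidity from temperature and dew point
#'
#' Magnus-Tetens form with constants (17.625, 243.04):
#' `RH = 100 * exp(17.625*Td/(243.04+Td)) / exp(17.625*T/(243.04+T))`,
#' clipped into (0, 100]. A dew point exceeding the temperature beyond
#' `tol` is physically inconsistent; it is clipped to 100% with a warning.
#'
#' @param tmean_c Daily mean temperature, degC.
#' @param tdew_c Daily mean dew-point temperature, degC.
#' @param tol Tolerance (degC) for `tdew > tmean` before warning.
#' @return Relative humidity in percent, vectorized; `NA` propagates.
#' @export
relative_humidity <- function(tmean_c, tdew_c, tol = 0.1) {
  bad <- !is.na(tmean_c) & !is.na(tdew_c) & (tdew_c > tmean_c + tol)
  if (any(bad))
    warning(sprintf("relative_humidity: %d dew points above temperature; clipped to 100%%",
                    sum(bad)))
  es <- function(t) exp(17.625 * t / (243.04 + t))
  rh <- 100 * es(tdew_c) / es(tmean_c)
  pmin(rh, 100)
}

#' Daily maximum 8-h running-mean ozone (MDA8)
#'
#' Scans the 24 eight-hour windows beginning at each local hour, borrowing
#' up to 7 hours from the following day. A window is computable when at
#' least 6 of its 8 hours are present (mean over present hours); the daily
#' value requires at least 18 of the 24 windows, otherwise `NA`.
#'
#' @param hourly Numeric vector of hourly concentrations for one local day
#'   plus up to 7 hours of the next day (length 24 to 31); `NA` = missing.
#' @param min_hours Minimum present hours per window (default 6).
#' @param min_windows Minimum computable windows per day (default 18).
#' @return The daily maximum 8-h mean, or `NA`.
#' @export
mda8 <- function(hourly, min_hours = 6, min_windows = 18) {
  stopifnot(length(hourly) >= 24, length(hourly) <= 31)
  means <- rep(NA_real_, 24)
  for (h in 1:24) {
    w <- hourly[h:min(h + 7, length(hourly))]
    if (length(w) < 8) w <- c(w, rep(NA_real_, 8 - length(w)))
    if (sum(!is.na(w)) >= min_hours) means[h] <- mean(w, na.rm = TRUE)
  }
  if (sum(!is.na(means)) < min_windows) return(NA_real_)
  max(means, na.rm = TRUE)
}

#' Longitude-based local-time offset
#'
#' The local time zone of a cell is taken as UTC + `round(lon/15)` hours,
#' a reproducible rule that needs no timezone database.
#'
#' @param lon Longitude in degrees.
#' @return Integer offset in hours.
#' @export
lon_utc_offset <- function(lon) as.integer(round(normalize_lon(lon) / 15))

#' Aggregate an hourly gridded series to local-time daily statistics
#'
#' Each cell's hourly series is shifted into its longitude-based local time
#' zone before the calendar-day grouping, so a "day" is a local day. A
#' cell-day with fewer than `ceiling(24 * min_frac)` present hours is `NA`.
#'
#' @param times POSIXct (UTC) hourly time stamps.
#' @param values Array `(time, lat, lon)` of hourly values.
#' @param grid The [grid_spec()] of `values`.
#' @param stat One of `"mean"`, `"min"`, `"max"`, `"sd"` (sample SD), `"sum"`.
#' @param min_frac Minimum fraction of the 24 hours required (default 0.75).
#' @return A [daily_field()] over the UTC calendar dates spanned by `times`.
#' @export
local_daily_stat <- function(times, values, grid, stat = "mean",
                             min_frac = 0.75) {
  stopifnot(inherits(times, "POSIXct"), length(times) == dim(values)[1])
  fn <- switch(stat,
               mean = function(v) mean(v),
               min  = function(v) min(v),
               max  = function(v) max(v),
               sd   = function(v) stats::sd(v),
               sum  = function(v) sum(v),
               stop("unknown stat: ", stat))
  need <- ceiling(24 * min_frac)
  dates <- seq(as.Date(min(times), tz = "UTC"), as.Date(max(times), tz = "UTC"),
               by = "day")
  out <- array(NA_real_, c(length(dates), grid$nlat, grid$nlon))
  lons <- grid_lons(grid)
  secs <- as.numeric(times)
  for (j in seq_len(grid$nlon)) {
    shift <- lon_utc_offset(lons[j]) * 3600
    ldate <- as.Date(as.POSIXct(secs + shift, origin = "1970-01-01", tz = "UTC"),
                     tz = "UTC")
    di <- match(ldate, dates)
    keep <- !is.na(di)
    for (i in seq_len(grid$nlat)) {
      v <- values[, i, j]
      agg <- tapply(v[keep], di[keep], function(x) {
        x <- x[!is.na(x)]
        if (length(x) < need) NA_real_ else fn(x)
      })
      out[as.integer(names(agg)), i, j] <- as.numeric(agg)
    }
  }
  daily_field(grid, dates, out, paste0("daily_", stat), units = "")
}

#' Derive the daily meteorological covariate fields from hourly inputs
#'
#' Produces the ten covariates used by the calibration models: Tmean, Tmax,
#' Tmin (degC), TV (sample SD of the 24 local-day hourly temperatures, degC),
#' RH (percent, Magnus form from daily mean temperature and dew point),
#' Wind_u, Wind_v (m/s daily means), Precip (daily total), Pressure (daily
#' mean) and UV (daily mean). All aggregation is by longitude-based local day.
#'
#' @param hourly Named list of hourly arrays `(time, lat, lon)`; required
#'   names: `t2m`, `d2m` (degC), `u10`, `v10`, `precip`, `pressure`, `uv`.
#' @param times POSIXct (UTC) stamps shared by all arrays.
#' @param grid The common [grid_spec()].
#' @return Named list of [daily_field()]s:
#'   `Tmean, Tmax, Tmin, TV, RH, Wind_u, Wind_v, Precip, Pressure, UV`.
#' @export
daily_met_from_hourly <- function(hourly, times, grid) {
  need <- c("t2m", "d2m", "u10", "v10", "precip", "pressure", "uv")
  if (!all(need %in% names(hourly)))
    stop("daily_met_from_hourly: hourly must contain ",
         paste(need, collapse = ", "))
  agg <- function(var, stat) local_daily_stat(times, hourly[[var]], grid, stat)
  tmean <- agg("t2m", "mean")
  tdew  <- agg("d2m", "mean")
  rh_vals <- relative_humidity(tmean$values, tdew$values)
  out <- list(
    Tmean    = tmean,
    Tmax     = agg("t2m", "max"),
    Tmin     = agg("t2m", "min"),
    TV       = agg("t2m", "sd"),
    RH       = daily_field(grid, tmean$dates, rh_vals, "RH", "%"),
    Wind_u   = agg("u10", "mean"),
    Wind_v   = agg("v10", "mean"),
    Precip   = agg("precip", "sum"),
    Pressure = agg("pressure", "mean"),
    UV       = agg("uv", "mean")
  )
  for (nm in names(out)) out[[nm]]$variable <- nm
  out
}
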