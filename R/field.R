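#' Daily gridded field
#'
#' A time-stack of one variable on a regular lat/lon grid: the universal
#' raster currency of the pipeline. Values are stored as a 3-d array indexed
#' `(date, lat, lon)` with latitudes ascending. Missing values are `NA`.
#'
#' @param grid A [grid_spec()].
#' @param dates A `Date` vector, strictly increasing.
#' @param values Numeric array of dim `c(length(dates), grid$nlat, grid$nlon)`.
#' @param variable Variable name (e.g. `"pm25_chem_total"`).
#' @param units Units string; concentrations are ug/m3.
#' @param nonneg If `TRUE`, all non-missing values must be >= 0.
#' @return An object of class `daily_field`.
#' @export
daily_field <- function(grid, dates, values, variable = "value",
                        units = "ug/m3", nonneg = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(dates, "Date"))
  if (length(dates) > 1 && any(diff(as.numeric(dates)) <= 0))
    stop("daily_field: dates must be strictly increasing")
  values <- as.array(values)
  if (length(dim(values)) != 3 ||
      !all(dim(values) == c(length(dates), grid$nlat, grid$nlon)))
    stop("daily_field: values must have dim (n_dates, nlat, nlon)")
  if (nonneg && any(values < 0, na.rm = TRUE))
    stop(sprintf("daily_field: negative values in non-negative variable '%s'",
                 variable))
  structure(list(grid = grid, dates = dates, values = values,
                 variable = variable, units = units, nonneg = nonneg),
            class = "daily_field")
}

#' @export
print.daily_field <- function(x, ...) {
  cat(sprintf("daily_field '%s' [%s]: %d dates (%s..%s) on %d x %d grid, %d NA\n",
              x$variable, x$units, length(x$dates),
              format(x$dates[1]), format(x$dates[length(x$dates)]),
              x$grid$nlat, x$grid$nlon, sum(is.na(x$values))))
  invisible(x)
}

check_aligned <- function(a, b, what = "fields") {
  if (!grids_equal(a$grid, b$grid) || length(a$dates) != length(b$dates) ||
      any(a$dates != b$dates))
    stop(sprintf("misaligned %s: grids/dates must match", what))
  invisible(TRUE)
}

#' Extract the daily series at one grid cell
#'
#' @param field A [daily_field()].
#' @param ilat,ilon Cell indices (1-based, latitude ascending).
#' @return Numeric vector over the field's dates.
#' @export
cell_series <- function(field, ilat, ilon) field$values[, ilat, ilon]

#' Block mean of a fine field onto a nesting coarse grid
#'
#' @param field A fine-grid [daily_field()].
#' @param coarse A [grid_spec()] whose cells are integer multiples of the
#'   fine cells.
#' @return A [daily_field()] on `coarse`; each coarse value is the mean of
#'   the fine cells it contains (`NA` ignored unless all missing).
#' @export
block_mean <- function(field, coarse) {
  idx <- nest_indices(field$grid, coarse)
  nd <- length(field$dates)
  out <- array(NA_real_, c(nd, coarse$nlat, coarse$nlon))
  for (ci in seq_len(coarse$nlat)) {
    rows <- which(idx$ilat == ci)
    if (!length(rows)) next
    for (cj in seq_len(coarse$nlon)) {
      cols <- which(idx$ilon == cj)
      if (!length(cols)) next
      block <- field$values[, rows, cols, drop = FALSE]
      out[, ci, cj] <- apply(block, 1, function(v) {
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      })
    }
  }
  daily_field(coarse, field$dates, out, field$variable, field$units)
}

# ---------------------------------------------------------------------------
# Gridded-field file format
#
# Self-describing plain text, one file per variable. Header lines carry the
# variable name, units, explicit coordinate vectors (lat, lon, time) in the
# style of CF coordinate variables, followed by one whitespace-separated row
# of nlon values per (date, lat). Doubles are printed with %.17g so a
# write-then-read round trip is bit-exact. Latitudes in the file may run in
# either direction; fields are always returned with ascending latitudes.
# ---------------------------------------------------------------------------

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

parse_nums <- function(line, path) {
  v <- strsplit(line, " ", fixed = TRUE)[[1]]
  out <- suppressWarnings(as.numeric(v))
  if (any(is.na(out) & v != "NA" & v != "NaN"))
    stop("format error: unparseable number in ", path)
  out
}

#' Write a daily field to a gridded text file
#'
#' @param field A [daily_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_field()]
#' @export
write_field <- function(field, path) {
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#gridded_field v1",
    paste("variable", field$variable),
    paste("units", field$units),
    paste("nonneg", if (field$nonneg) "1" else "0"),
    paste("lat", paste(fmt_num(grid_lats(g)), collapse = " ")),
    paste("lon", paste(fmt_num(grid_lons(g)), collapse = " ")),
    paste("time", paste(format(field$dates, "%Y-%m-%d"), collapse = " "))
  ), con)
  nd <- length(field$dates)
  for (t in seq_len(nd))
    for (i in seq_len(g$nlat))
      writeLines(paste(fmt_num(field$values[t, i, ]), collapse = " "), con)
  invisible(path)
}

#' Read a daily field from a gridded text file
#'
#' Validates that lat/lon/time coordinate blocks are present and that the
#' lat/lon spacings are regular to within 1e-6 degrees; files with descending
#' latitudes are reordered to the package's ascending convention.
#'
#' @param path File written by [write_field()].
#' @param variable Optional expected variable name; mismatch is an error.
#' @return A [daily_field()].
#' @export
read_field <- function(path, variable = NULL) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "#gridded_field v1")
    stop("format error: not a gridded_field file: ", path)
  hdr <- list()
  i <- 2
  while (i <= length(lines) && grepl("^(variable|units|nonneg|lat|lon|time) ", lines[i])) {
    key <- sub(" .*", "", lines[i])
    hdr[[key]] <- sub("^[a-z]+ ", "", lines[i])
    i <- i + 1
  }
  for (key in c("lat", "lon", "time"))
    if (is.null(hdr[[key]]))
      stop("format error: missing ", key, " coordinate in ", path)
  lats <- parse_nums(hdr$lat, path)
  lons <- parse_nums(hdr$lon, path)
  dates <- as.Date(strsplit(hdr$time, " ")[[1]])
  if (anyNA(dates)) stop("format error: unparseable time coordinate in ", path)
  check_regular <- function(x, what) {
    if (length(x) > 1) {
      d <- diff(x)
      if (max(abs(d - d[1])) > 1e-6)
        stop("format error: irregular ", what, " spacing in ", path)
    }
  }
  check_regular(lats, "latitude"); check_regular(lons, "longitude")
  desc <- length(lats) > 1 && lats[2] < lats[1]
  if (desc) lats_asc <- rev(lats) else lats_asc <- lats
  dlat <- if (length(lats) > 1) abs(lats[2] - lats[1]) else 1
  dlon <- if (length(lons) > 1) lons[2] - lons[1] else 1
  g <- grid_spec(lats_asc[1], lons[1], dlat, dlon, length(lats), length(lons))
  nd <- length(dates)
  body <- lines[i:length(lines)]
  if (length(body) != nd * g$nlat)
    stop("format error: expected ", nd * g$nlat, " data rows, found ",
         length(body), " in ", path)
  vals <- array(NA_real_, c(nd, g$nlat, g$nlon))
  row <- 0
  for (t in seq_len(nd)) for (ii in seq_len(g$nlat)) {
    row <- row + 1
    v <- parse_nums(body[row], path)
    if (length(v) != g$nlon)
      stop("format error: row width mismatch in ", path)
    target <- if (desc) g$nlat - ii + 1L else ii
    vals[t, target, ] <- v
  }
  fld <- daily_field(g, dates, vals, hdr$variable %||% "value",
                     hdr$units %||% "", identical(hdr$nonneg, "1"))
  if (!is.null(variable) && fld$variable != variable)
    stop("format error: file holds variable '", fld$variable,
         "', expected '", variable, "'")
  fld
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Station tables
# ---------------------------------------------------------------------------

#' Construct / validate a station observation table
#'
#' One row per station-date. Pollutant is `"pm25"` (daily mean) or `"o3"`
#' (daily max 8 h); concentrations in ug/m3, `NA` for missing, otherwise
#' non-negative.
#'
#' @param station_id Character or integer station identifiers.
#' @param lon,lat Station coordinates, degrees.
#' @param date `Date` of observation.
#' @param pollutant `"pm25"` or `"o3"`.
#' @param value_ugm3 Observed concentration.
#' @return A `data.frame` of class `station_series`.
#' @export
station_series <- function(station_id, lon, lat, date, pollutant, value_ugm3) {
  df <- data.frame(station_id = as.character(station_id),
                   lon = normalize_lon(lon), lat = lat,
                   date = as.Date(date),
                   pollutant = pollutant, value_ugm3 = value_ugm3,
                   stringsAsFactors = FALSE)
  if (!all(df$pollutant %in% c("pm25", "o3")))
    stop("station_series: pollutant must be 'pm25' or 'o3'")
  if (!all(is.finite(df$lon)) || !all(is.finite(df$lat)))
    stop("station_series: station coordinates must be finite")
  if (any(df$value_ugm3 < 0, na.rm = TRUE))
    stop("station_series: concentrations must be >= 0 or NA")
  if (anyDuplicated(df[c("station_id", "pollutant", "date")]))
    stop("station_series: one record per station-date required")
  class(df) <- c("station_series", "data.frame")
  df
}

#' Read / write station tables as CSV
#'
#' Columns: `station_id, lon, lat, date` (ISO-8601), `pollutant, value_ugm3`.
#'
#' @param path CSV file path.
#' @return [read_stations()] returns a `station_series`;
#'   [write_stations()] returns `path` invisibly.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "date", "pollutant", "value_ugm3")
  if (!all(need %in% names(df)))
    stop("format error: station CSV must have columns ",
         paste(need, collapse = ", "))
  station_series(df$station_id, df$lon, df$lat, df$date, df$pollutant,
                 df$value_ugm3)
}

#' @rdname read_stations
#' @param stations A `station_series`.
#' @export
write_stations <- function(stations, path) {
  df <- as.data.frame(stations)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-station coordinate table
#'
#' @param stations A `station_series`.
#' @return `data.frame` with one row per station: `station_id, lon, lat`.
#' @export
station_locations <- function(stations) {
  u <- unique(as.data.frame(stations)[c("station_id", "lon", "lat")])
  u[order(u$station_id), , drop = FALSE]
}
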