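# Calibration of downscaled chemical-transport fields against station
# observations, and fire-source attribution by ratio scaling. The calibrated
# all-source concentration is a random-forest regression of station
# observations on the downscaled chem field, ten meteorological covariates
# and six space-time terms; the fire-sourced share is then the calibrated
# total times the chem-simulation fire fraction.

CALIBRATION_FEATURES <- c("chem_total", "Tmean", "Tmax", "Tmin", "TV", "RH",
                          "Wind_u", "Wind_v", "Precip", "Pressure", "UV",
                          "Year", "Month", "DOW", "DOY", "Lon", "Lat")

calendar_frame <- function(dates) {
  lt <- as.POSIXlt(dates)
  data.frame(Year = lt$year + 1900,
             Month = lt$mon + 1L,
             DOW = ifelse(lt$wday == 0L, 7L, lt$wday),  # Monday-first 1..7
             DOY = lt$yday + 1L)
}

#' Assemble the station-day training table
#'
#' Links each station to its grid cell and pairs every station-day
#' observation with the 17 predictors: the downscaled all-source chem
#' concentration, the ten meteorological covariates sampled at the station's
#' cell, and Year, Month, DOW (Monday = 1), DOY, Lon, Lat (station
#' coordinates). Rows with a missing response or any missing predictor are
#' dropped; stations outside the grid are excluded with a warning.
#'
#' @param stations A `station_series` (one pollutant).
#' @param chem_total_fine Downscaled all-source chem [daily_field()].
#' @param covariates Named list of the ten covariate [daily_field()]s
#'   (`Tmean`..`UV`), aligned with `chem_total_fine`.
#' @return A `data.frame` with columns `station_id, date, obs` plus the 17
#'   predictors, of class `training_table`.
#' @export
assemble_training <- function(stations, chem_total_fine, covariates) {
  g <- chem_total_fine$grid
  for (nm in names(covariates)) check_aligned(chem_total_fine, covariates[[nm]])
  locs <- station_locations(stations)
  dates <- chem_total_fine$dates
  cal <- calendar_frame(dates)
  rows <- vector("list", nrow(locs))
  dropped <- character()
  sdf <- as.data.frame(stations)
  for (si in seq_len(nrow(locs))) {
    cell <- tryCatch(locate_cell(g, locs$lon[si], locs$lat[si]),
                     error = function(e) NULL)
    if (is.null(cell)) { dropped <- c(dropped, locs$station_id[si]); next }
    srows <- sdf[sdf$station_id == locs$station_id[si], ]
    di <- match(srows$date, dates)
    ok <- !is.na(di)
    srows <- srows[ok, ]; di <- di[ok]
    df <- data.frame(station_id = srows$station_id, date = srows$date,
                     obs = srows$value_ugm3,
                     chem_total = chem_total_fine$values[cbind(di, cell[1], cell[2])])
    for (nm in names(covariates))
      df[[nm]] <- covariates[[nm]]$values[cbind(di, cell[1], cell[2])]
    df <- cbind(df, cal[di, , drop = FALSE])
    df$Lon <- locs$lon[si]; df$Lat <- locs$lat[si]
    rows[[si]] <- df
  }
  if (length(dropped))
    warning("assemble_training: stations outside grid excluded: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[stats::complete.cases(out[c("obs", CALIBRATION_FEATURES)]), ]
  class(out) <- c("training_table", "data.frame")
  out
}

#' Fit the random-forest calibration model
#'
#' A seeded ranger regression of station observations on the 17 predictors.
#' When `mtry` is `NULL` it is selected by k-fold CV RMSE over the grid
#' `c(3, 5, 7, 9)`; refitting with the same table and seed reproduces
#' identical predictions.
#'
#' @param table A [assemble_training()] result (>= 50 rows).
#' @param num_trees Number of trees (default 500).
#' @param mtry Variables per split, or `NULL` to tune.
#' @param min_node_size Minimum leaf size (default 5).
#' @param cv_folds Folds for `mtry` tuning (default 10).
#' @param seed Integer seed.
#' @return An object of class `calibration_model`: the fitted forest, the
#'   ordered feature list, response range and training metadata.
#' @export
fit_calibration <- function(table, num_trees = 500, mtry = NULL,
                            min_node_size = 5, cv_folds = 10, seed = 1L) {
  if (nrow(table) < 50) stop("fit_calibration: need >= 50 training rows")
  if (any(table$obs < 0)) stop("fit_calibration: negative responses")
  if (stats::var(table$obs) == 0)
    warning("fit_calibration: constant response; degenerate fit")
  dat <- as.data.frame(table)[c("obs", CALIBRATION_FEATURES)]
  cv_rmse <- NULL
  if (is.null(mtry)) {
    grid <- c(3, 5, 7, 9)
    set.seed(seed)
    fold <- sample(rep_len(seq_len(cv_folds), nrow(dat)))
    rmse <- vapply(grid, function(m) {
      errs <- vapply(seq_len(cv_folds), function(f) {
        fit <- ranger::ranger(obs ~ ., data = dat[fold != f, ],
                              num.trees = max(100, num_trees %/% 5),
                              mtry = m, min.node.size = min_node_size,
                              seed = seed, num.threads = 1)
        p <- stats::predict(fit, dat[fold == f, ],
                            num.threads = 1, verbose = FALSE)$predictions
        sqrt(mean((p - dat$obs[fold == f])^2))
      }, 0)
      mean(errs)
    }, 0)
    mtry <- grid[which.min(rmse)]
    cv_rmse <- stats::setNames(rmse, grid)
  }
  fit <- ranger::ranger(obs ~ ., data = dat, num.trees = num_trees,
                        mtry = mtry, min.node.size = min_node_size,
                        seed = seed, num.threads = 1)
  structure(list(forest = fit, features = CALIBRATION_FEATURES,
                 response_range = range(dat$obs),
                 hyperparams = list(num_trees = num_trees, mtry = mtry,
                                    min_node_size = min_node_size),
                 cv_rmse = cv_rmse, seed = seed),
            class = "calibration_model")
}

#' Predict on a predictor data frame
#'
#' @param object A `calibration_model`.
#' @param newdata Data frame containing the model's features.
#' @param ... Unused.
#' @return Numeric predictions (finite, within the training response range).
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  if (!all(object$features %in% names(newdata)))
    stop("calibration_model: feature mismatch; need ",
         paste(setdiff(object$features, names(newdata)), collapse = ", "))
  stats::predict(object$forest, newdata[object$features],
                 num.threads = 1, verbose = FALSE)$predictions
}

#' Calibrated all-source concentration on the full grid
#'
#' Applies the fitted calibration model at every cell-date, using cell-center
#' coordinates as the Lon/Lat predictors. Cell-dates with any missing
#' predictor yield `NA`.
#'
#' @param model A [fit_calibration()] result.
#' @param chem_total_fine Downscaled all-source chem [daily_field()].
#' @param covariates Named list of covariate fields, as in
#'   [assemble_training()].
#' @return A [daily_field()] of calibrated (bias-corrected) concentration.
#' @export
predict_total <- function(model, chem_total_fine, covariates) {
  g <- chem_total_fine$grid
  for (nm in names(covariates)) check_aligned(chem_total_fine, covariates[[nm]])
  dates <- chem_total_fine$dates
  nd <- length(dates); ncell <- g$nlat * g$nlon
  cal <- calendar_frame(dates)
  # rows ordered cell-major: all dates of cell 1, then cell 2, ...
  lats <- rep(grid_lats(g), times = g$nlon)
  lons <- rep(grid_lons(g), each = g$nlat)
  nd_rep <- rep(seq_len(nd), ncell)
  newdata <- data.frame(
    chem_total = as.vector(chem_total_fine$values),
    stringsAsFactors = FALSE)
  for (nm in names(covariates))
    newdata[[nm]] <- as.vector(covariates[[nm]]$values)
  newdata <- cbind(newdata, cal[nd_rep, , drop = FALSE])
  newdata$Lon <- rep(lons, each = nd)
  newdata$Lat <- rep(lats, each = nd)
  ok <- stats::complete.cases(newdata[model$features])
  pred <- rep(NA_real_, nrow(newdata))
  if (any(ok)) pred[ok] <- predict(model, newdata[ok, , drop = FALSE])
  daily_field(g, dates, array(pred, c(nd, g$nlat, g$nlon)),
              paste0(chem_total_fine$variable, "_calibrated"), "ug/m3")
}

#' Fire fraction of the chem simulation
#'
#' Ratio of the fire-sourced to the all-source chem field per cell-date,
#' defined as 0 where the all-source field is 0 (no fire signal
#' attributable), and clipped into [-1, 1]; the number of clipped cell-dates
#' is attached as attribute `"n_clipped"`. Negative fractions (fire-driven
#' O3 deficits) are retained.
#'
#' @param chem_fire,chem_total Aligned [daily_field()]s.
#' @return A [daily_field()] of the dimensionless fraction.
#' @export
fire_fraction <- function(chem_fire, chem_total) {
  check_aligned(chem_fire, chem_total)
  tot <- chem_total$values; fire <- chem_fire$values
  frac <- ifelse(is.na(tot) | is.na(fire), NA_real_,
                 ifelse(tot == 0, 0, fire / tot))
  n_clip <- sum(frac < -1 | frac > 1, na.rm = TRUE)
  if (n_clip > 0)
    message("fire_fraction: clipped ", n_clip, " cell-dates into [-1, 1]")
  frac <- pmin(pmax(frac, -1), 1)
  out <- daily_field(chem_total$grid, chem_total$dates, frac,
                     "fire_fraction", "")
  attr(out, "n_clipped") <- n_clip
  out
}

#' Fire-sourced concentration by ratio scaling
#'
#' The final fire-sourced estimate: calibrated all-source concentration
#' times the chem fire fraction, pointwise. Wherever the calibrated total is
#' positive, the fire share of the output equals the chem fraction exactly.
#'
#' @param est_total Calibrated all-source [daily_field()].
#' @param fraction A [fire_fraction()] result.
#' @return A [daily_field()] of fire-sourced concentration.
#' @export
scale_fire <- function(est_total, fraction) {
  check_aligned(est_total, fraction)
  daily_field(est_total$grid, est_total$dates,
              est_total$values * fraction$values,
              sub("_total", "_fire", est_total$variable, fixed = TRUE),
              est_total$units)
}

#' Save / load a calibration model artifact
#'
#' The artifact embeds the feature list, hyperparameters and seed, so a
#' loaded model predicts identically to the original.
#'
#' @param model A `calibration_model`.
#' @param path Artifact path.
#' @return `path` / the restored `calibration_model`.
#' @export
save_calibration <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "calibration_model"))
    stop("load_calibration: not a calibration model artifact")
  m
}
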