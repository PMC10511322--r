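# Validation machinery: ordinary/spatial tenfold CV, k-means station
# clustering with leave-one-cluster-out CV, pooled and two-way fixed-effects
# (within) R2, station-specific R2 summaries, the background-median smoke
# observation operator, and wildfire-event station selection.

#' Build a cross-validation partition
#'
#' `row_kfold` partitions station-day rows at random; `station_kfold`
#' partitions stations and assigns each station's rows to its station's
#' fold, so no station is split across folds (the spatial scheme);
#' `station_cluster` takes externally supplied cluster labels per station.
#' Fold sizes are within one unit (rows or stations) of equal.
#'
#' @param table A training table with a `station_id` column.
#' @param scheme `"row_kfold"`, `"station_kfold"` or `"station_cluster"`.
#' @param k Number of folds (>= 2); ignored for `station_cluster`.
#' @param seed Integer seed.
#' @param clusters For `station_cluster`: named vector of cluster labels,
#'   names = station ids.
#' @return Object of class `cv_partition`: integer fold label per row.
#' @export
make_partition <- function(table, scheme = c("row_kfold", "station_kfold",
                                             "station_cluster"),
                           k = 10, seed = 1L, clusters = NULL) {
  scheme <- match.arg(scheme)
  n <- nrow(table)
  if (scheme == "row_kfold") {
    if (k > n) stop("partition error: k exceeds number of rows")
    set.seed(seed)
    fold <- sample(rep_len(seq_len(k), n))
  } else if (scheme == "station_kfold") {
    ids <- sort(unique(table$station_id))
    if (k > length(ids)) stop("partition error: k exceeds number of stations")
    set.seed(seed)
    sf <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
    fold <- as.integer(sf[table$station_id])
  } else {
    if (is.null(clusters)) stop("partition error: station_cluster needs cluster labels")
    fold <- as.integer(factor(clusters[table$station_id]))
    if (anyNA(fold)) stop("partition error: stations without a cluster label")
  }
  if (length(unique(fold)) < 2) stop("partition error: fewer than 2 nonempty folds")
  structure(list(scheme = scheme, fold = fold, k = length(unique(fold)),
                 seed = seed), class = "cv_partition")
}

pooled_metrics <- function(obs, pred) {
  ok <- !is.na(obs) & !is.na(pred)
  obs <- obs[ok]; pred <- pred[ok]
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  list(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((obs - pred)^2)), n = length(obs))
}

#' A ranger fit function for cross-validation
#'
#' Returns a closure suitable for [cross_validate()]: fits a seeded forest
#' on the training rows and predicts new rows.
#'
#' @param num_trees,mtry,min_node_size,seed Forest hyperparameters.
#' @return `function(train) -> function(newdata) -> predictions`.
#' @export
rf_fit_fn <- function(num_trees = 500, mtry = 5, min_node_size = 5, seed = 1L) {
  force(num_trees); force(mtry); force(min_node_size); force(seed)
  function(train) {
    fit <- ranger::ranger(obs ~ ., data = as.data.frame(train)[c("obs", CALIBRATION_FEATURES)],
                          num.trees = num_trees, mtry = mtry,
                          min.node.size = min_node_size, seed = seed,
                          num.threads = 1)
    function(newdata)
      stats::predict(fit, as.data.frame(newdata)[CALIBRATION_FEATURES],
                     num.threads = 1, verbose = FALSE)$predictions
  }
}

#' Cross-validate a fit function over a partition
#'
#' Each fold is held out once; the model fitted on the remaining folds
#' predicts it, so every row receives exactly one out-of-fold prediction.
#' Pooled metrics are computed over the concatenated out-of-fold
#' predictions; per-fold metrics and the prediction table are returned for
#' downstream station-level and fixed-effects summaries.
#'
#' @param table Training table (`obs` + predictors + `station_id`, `date`).
#' @param partition A [make_partition()] result for `table`.
#' @param fit_fn `function(train)` returning a prediction
#'   `function(newdata)`; see [rf_fit_fn()].
#' @return Object of class `cv_result`: `r2`, `rmse`, `n`, `per_fold`
#'   data frame, and `predictions` (station_id, date, fold, obs, pred).
#' @export
cross_validate <- function(table, partition, fit_fn) {
  stopifnot(inherits(partition, "cv_partition"),
            length(partition$fold) == nrow(table))
  pred <- rep(NA_real_, nrow(table))
  folds <- sort(unique(partition$fold))
  per_fold <- data.frame()
  for (f in folds) {
    hold <- partition$fold == f
    if (all(hold)) stop("scheme error: fold ", f, " leaves no training data")
    pf <- fit_fn(table[!hold, , drop = FALSE])
    pred[hold] <- pf(table[hold, , drop = FALSE])
    m <- pooled_metrics(table$obs[hold], pred[hold])
    per_fold <- rbind(per_fold,
                      data.frame(fold = f, n = m$n, r2 = m$r2, rmse = m$rmse))
  }
  m <- pooled_metrics(table$obs, pred)
  structure(list(r2 = m$r2, rmse = m$rmse, n = m$n, per_fold = per_fold,
                 predictions = data.frame(
                   station_id = table$station_id, date = table$date,
                   fold = partition$fold, obs = table$obs, pred = pred,
                   stringsAsFactors = FALSE),
                 scheme = partition$scheme),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result (%s): R2 = %.3f, RMSE = %.3f, n = %d, %d folds\n",
              x$scheme, x$r2, x$rmse, x$n, nrow(x$per_fold)))
  invisible(x)
}

#' Cluster monitoring stations by k-means on longitude/latitude
#'
#' Seeded k-means (Euclidean, degree space, multiple restarts). When `k` is
#' a vector, the number of clusters is chosen by the elbow rule: the k with
#' the maximum second difference of within-group sum of squares.
#'
#' @param locations Data frame with `station_id, lon, lat` (see
#'   [station_locations()]).
#' @param k Integer cluster count, or a vector of candidate counts.
#' @param seed Integer seed.
#' @param nstart Random restarts (default 25).
#' @return Named integer vector of cluster labels (names = station ids),
#'   with chosen `k` and total within-SS as attributes.
#' @export
kmeans_station_clusters <- function(locations, k, seed = 1L, nstart = 25) {
  xy <- as.matrix(locations[c("lon", "lat")])
  if (nrow(unique(xy)) < max(k))
    stop("clustering error: fewer distinct station coordinates than k")
  run <- function(kk) {
    if (kk >= nrow(unique(xy))) {
      # degenerate k: every distinct location is its own cluster
      lab <- as.integer(factor(apply(xy, 1, paste, collapse = ",")))
      return(list(cluster = lab, tot.withinss = 0))
    }
    set.seed(seed)
    stats::kmeans(xy, centers = kk, nstart = nstart, iter.max = 100)
  }
  if (length(k) > 1) {
    k <- sort(k)
    wss <- vapply(k, function(kk) run(kk)$tot.withinss, 0)
    if (length(k) >= 3) {
      d2 <- diff(diff(wss))            # second difference of the WSS curve
      kk <- k[which.max(d2) + 1L]
    } else kk <- k[which.min(wss)]
  } else kk <- k
  km <- run(kk)
  labels <- stats::setNames(km$cluster, locations$station_id)
  attr(labels, "k") <- kk
  attr(labels, "tot_withinss") <- km$tot.withinss
  labels
}

#' Leave-one-cluster-out cross-validation
#'
#' One fit per spatial cluster, holding the whole cluster out: the sternest
#' test of generalization to regions without training stations. Singleton
#' clusters are flagged in the per-fold table.
#'
#' @param table Training table.
#' @param clusters Named cluster labels from [kmeans_station_clusters()].
#' @param fit_fn As in [cross_validate()].
#' @return A `cv_result` (fold = cluster).
#' @export
cluster_loocv <- function(table, clusters, fit_fn) {
  if (length(unique(clusters)) < 2)
    stop("scheme error: need >= 2 clusters")
  part <- make_partition(table, "station_cluster", clusters = clusters)
  res <- cross_validate(table, part, fit_fn)
  n_stations <- tapply(names(clusters), clusters, length)
  res$per_fold$singleton <- as.vector(n_stations[as.character(res$per_fold$fold)] == 1)
  res
}

#' Two-way fixed-effects within-R2
#'
#' R2 of the regression of observations on estimates after removing two
#' grouping structures (e.g. station and year, or coarse block and date)
#' by iterated two-way demeaning (converged to 1e-10). Equals the
#' dummy-variable OLS partial R2 of the estimate. Measures how much *local
#' temporal* variation the estimates explain, not cross-site level
#' differences.
#'
#' @param obs,est Numeric vectors.
#' @param group1,group2 Grouping vectors (>= 2 levels each).
#' @param tol Demeaning convergence tolerance.
#' @return The within-R2; `NaN` (with a warning) if the estimate is
#'   absorbed by the fixed effects.
#' @export
within_r2 <- function(obs, est, group1, group2, tol = 1e-10) {
  ok <- !is.na(obs) & !is.na(est) & !is.na(group1) & !is.na(group2)
  obs <- obs[ok]; est <- est[ok]
  g1 <- as.factor(group1[ok]); g2 <- as.factor(group2[ok])
  if (nlevels(droplevels(g1)) < 2 || nlevels(droplevels(g2)) < 2)
    stop("within_r2: each grouping needs >= 2 levels")
  demean <- function(x) {
    repeat {
      x_new <- x - stats::ave(x, g1)
      x_new <- x_new - stats::ave(x_new, g2)
      if (max(abs(x_new - x)) < tol) return(x_new)
      x <- x_new
    }
  }
  y <- demean(obs); x <- demean(est)
  sxx <- sum(x^2)
  if (sxx < 1e-12 * max(1, sum(est^2))) {
    warning("within_r2: estimate absorbed by the fixed effects")
    return(NaN)
  }
  sum(x * y)^2 / (sxx * sum(y^2))
}

#' Station-specific R2 of out-of-fold predictions
#'
#' Per-station R2 against the station's own mean, for stations with at
#' least `min_obs` predictions; summarized by the median and the 10th
#' percentile (the floor below which only 10% of stations fall).
#'
#' @param predictions Prediction table from a `cv_result`.
#' @param min_obs Minimum station-days per reported station (default 30).
#' @return List: `per_station` data frame (`station_id, n, r2`), `median`,
#'   `q10`, and `n_excluded`.
#' @export
station_r2 <- function(predictions, min_obs = 30) {
  sp <- split(predictions, predictions$station_id)
  rows <- lapply(sp, function(d) {
    d <- d[!is.na(d$obs) & !is.na(d$pred), ]
    if (nrow(d) < min_obs) return(NULL)
    ss_tot <- sum((d$obs - mean(d$obs))^2)
    r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((d$obs - d$pred)^2) / ss_tot
    data.frame(station_id = d$station_id[1], n = nrow(d), r2 = r2,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  excl <- length(sp) - NROW(per)
  if (is.null(per))
    return(list(per_station = data.frame(), median = NA_real_, q10 = NA_real_,
                n_excluded = excl))
  rownames(per) <- NULL
  list(per_station = per,
       median = stats::median(per$r2, na.rm = TRUE),
       q10 = unname(stats::quantile(per$r2, 0.10, na.rm = TRUE)),
       n_excluded = excl)
}

#' Observed smoke PM2.5 by the background-median method
#'
#' For each station-day flagged as a smoke day, the smoke PM2.5 is the
#' observation minus the station- and month-specific median of non-smoke-day
#' observations pooled over the previous, current and next calendar years,
#' floored at zero. Smoke PM2.5 on non-smoke days is 0 by convention.
#' Smoke days with no non-smoke observation in their 3-year month window
#' get `NA` background.
#'
#' @param stations A `station_series` of PM2.5 observations.
#' @param smoke_days Data frame `station_id, date` of smoke-day flags
#'   (station-days not listed are non-smoke days).
#' @return Data frame `station_id, date, obs, smoke_day, background,
#'   smoke_pm25`.
#' @export
observed_smoke_pm <- function(stations, smoke_days) {
  df <- as.data.frame(stations)
  key <- paste(df$station_id, df$date)
  skey <- paste(smoke_days$station_id, as.Date(smoke_days$date))
  df$smoke_day <- key %in% skey
  df$year <- as.integer(format(df$date, "%Y"))
  df$month <- as.integer(format(df$date, "%m"))
  df$background <- NA_real_
  df$smoke_pm25 <- 0
  smoke_idx <- which(df$smoke_day & !is.na(df$value_ugm3))
  for (i in smoke_idx) {
    w <- df$station_id == df$station_id[i] & !df$smoke_day &
      df$month == df$month[i] & abs(df$year - df$year[i]) <= 1 &
      !is.na(df$value_ugm3)
    if (!any(w)) { df$smoke_pm25[i] <- NA_real_; next }
    bg <- stats::median(df$value_ugm3[w])
    df$background[i] <- bg
    df$smoke_pm25[i] <- max(df$value_ugm3[i] - bg, 0)
  }
  df[c("station_id", "date", "value_ugm3", "smoke_day", "background",
       "smoke_pm25")]
}

#' Most affected station near a wildfire event
#'
#' Among stations within `radius_km` of the event with observations in both
#' windows, selects the one with the largest increase in mean observed
#' concentration from the pre-event window to the event window; ties break
#' to the smaller station id.
#'
#' @param stations A `station_series`.
#' @param event_lon,event_lat Event location, degrees.
#' @param event_window,pre_window `Date` vectors of the two windows.
#' @param radius_km Search radius (default 100).
#' @return List: `station_id`, `increase`, and the per-station table.
#' @export
most_affected_station <- function(stations, event_lon, event_lat,
                                  event_window, pre_window,
                                  radius_km = 100) {
  locs <- station_locations(stations)
  locs$dist_km <- great_circle_km(locs$lon, locs$lat, event_lon, event_lat)
  cand <- locs[locs$dist_km <= radius_km, ]
  df <- as.data.frame(stations)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    d <- df[df$station_id == cand$station_id[i], ]
    ev <- d$value_ugm3[d$date %in% as.Date(event_window)]
    pr <- d$value_ugm3[d$date %in% as.Date(pre_window)]
    ev <- ev[!is.na(ev)]; pr <- pr[!is.na(pr)]
    if (!length(ev) || !length(pr)) return(NULL)
    data.frame(station_id = cand$station_id[i], dist_km = cand$dist_km[i],
               increase = mean(ev) - mean(pr), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab))
    stop("selection error: no station within radius with data in both windows")
  tab <- tab[order(-tab$increase, tab$station_id), ]
  list(station_id = tab$station_id[1], increase = tab$increase[1],
       stations = tab)
}
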