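# Replicated evaluation studies: the calibration-gain experiment that
# motivates the whole pipeline (does station calibration beat the raw
# downscaled chem field out of sample?) and the statistical calibration of
# the trend tests. These are the package's standing experiments; tests and
# the acceptance script run them rather than re-implementing them.

#' Replicated calibration-gain study
#'
#' For each replicate, generates a fresh synthetic world, downscales the
#' coarse all-source PM2.5 chem field, and compares three out-of-sample
#' accuracies at the stations: spatial (station) tenfold CV of the
#' random-forest calibration, the raw downscaled chem field, and
#' leave-one-cluster-out CV over k-means station clusters. The expected
#' pattern mirrors the pipeline's premise: calibrated beats raw, and
#' cluster-held-out generalization is the harder task.
#'
#' The replicate worlds use a 24 x 30 cell domain with 180 days and 36
#' PM2.5 stations: large enough for the effect to be stable, small enough
#' to replicate twenty times on one CPU.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate seeds are derived substreams.
#' @param num_trees Trees per forest.
#' @param k Folds for the spatial tenfold CV.
#' @param n_clusters k-means clusters for the cluster CV.
#' @param world_args Overrides for the replicate [world_config()].
#' @return Data frame with one row per replicate: `rep, r2_calibrated,
#'   r2_raw, r2_cluster, n_rows`.
#' @export
calibration_gain_study <- function(n_reps = 20, seed = 1L, num_trees = 100,
                                   k = 10, n_clusters = 6,
                                   world_args = list()) {
  defaults <- list(nlat_fine = 24, nlon_fine = 30, n_days = 180,
                   n_stations_pm = 36, n_stations_o3 = 5,
                   n_station_clusters = 6, n_countries = 4)
  defaults[names(world_args)] <- world_args
  out <- data.frame()
  for (i in seq_len(n_reps)) {
    rs <- seed_for(seed, paste0("gain_rep_", i))
    w <- make_world(do.call(world_config, c(defaults, list(seed = rs))))
    fine <- idw_downscale(w$chem$pm_total, w$grid)
    tab <- assemble_training(w$stations$pm, fine, w$covariates)
    part <- make_partition(tab, "station_kfold", k = k, seed = rs)
    fitfn <- rf_fit_fn(num_trees = num_trees, mtry = 5, seed = rs)
    cv <- cross_validate(tab, part, fitfn)
    raw <- pooled_metrics(tab$obs, tab$chem_total)
    cl <- kmeans_station_clusters(station_locations(w$stations$pm),
                                  k = n_clusters, seed = rs)
    ccv <- cluster_loocv(tab, cl, fitfn)
    out <- rbind(out, data.frame(rep = i, r2_calibrated = cv$r2,
                                 r2_raw = raw$r2, r2_cluster = ccv$r2,
                                 n_rows = nrow(tab)))
  }
  out
}

#' Slope-recovery calibration of the annual trend test
#'
#' Simulates annual metric series with a planted linear trend plus Gaussian
#' noise and checks how often the 95% confidence interval of the fitted
#' slope covers the planted value (nominally 95%).
#'
#' @param n_reps Number of simulated series.
#' @param seed Integer seed.
#' @param years Calendar years of each series.
#' @param slope_per_decade Planted slope (units per decade).
#' @param noise_sd SD of the annual noise.
#' @return List: `coverage` (fraction covered), `n_reps`.
#' @export
trend_recovery_study <- function(n_reps = 200, seed = 1L, years = 2000:2019,
                                 slope_per_decade = 0.5, noise_sd = 1) {
  set.seed(seed_for(seed, "trend_recovery"))
  b <- slope_per_decade / 10
  hits <- 0
  for (i in seq_len(n_reps)) {
    vals <- 10 + b * (years - years[1]) + stats::rnorm(length(years), 0, noise_sd)
    tf <- fit_trend(years, vals)
    if (tf$ci95[1] <= b && b <= tf$ci95[2]) hits <- hits + 1
  }
  list(coverage = hits / n_reps, n_reps = n_reps)
}

#' Type-I error of the per-cell trend test under a null world
#'
#' Fits per-cell trends to pure-noise annual values and reports the
#' fraction of cells significant at p < 0.05 (nominally 0.05).
#'
#' @param n_cells Number of null cells.
#' @param n_years Years per cell.
#' @param seed Integer seed.
#' @return List: `rate`, `n_cells`, `se` (binomial standard error at 0.05).
#' @export
trend_type1_study <- function(n_cells = 1000, n_years = 20, seed = 1L) {
  set.seed(seed_for(seed, "trend_null"))
  nlat <- 10; nlon <- n_cells / nlat
  vals <- array(stats::rnorm(n_years * n_cells, 20, 3),
                c(n_years, nlat, nlon))
  tr <- grid_trends(list(years = seq_len(n_years) + 1999, values = vals))
  list(rate = mean(tr$p < 0.05, na.rm = TRUE), n_cells = n_cells,
       se = sqrt(0.05 * 0.95 / n_cells))
}
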