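# Seeded synthetic world generator. Emulates the statistical structure the
# pipeline assumes -- a smooth spatio-seasonal pollution baseline plus
# episodic fire plumes as truth, coarse chemical-transport output as a
# biased/noisy block mean of that truth with a companion fire field,
# covariates that carry real information about truth, a clustered station
# network, and a population raster split into contiguous synthetic countries
# with UN-style reference totals -- so every downstream stage has a known
# answer without any external data.

seed_for <- function(seed, name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 1000003
  as.integer(((seed %% 1000003) * 1009 + h) %% 2147483647)
}

# smooth random surface: a few low-frequency cosine modes, standardized
smooth_surface <- function(nlat, nlon, n_modes = 4) {
  y <- seq(0, 1, length.out = nlat)
  x <- seq(0, 1, length.out = nlon)
  f <- matrix(0, nlat, nlon)
  for (k in seq_len(n_modes)) {
    fy <- stats::runif(1, 0.5, 2.5); fx <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi); a <- stats::rnorm(1)
    f <- f + a * outer(cos(2 * pi * fy * y + ph[1]),
                       cos(2 * pi * fx * x + ph[2]))
  }
  s <- stats::sd(f)
  if (!is.finite(s) || s == 0) return(matrix(0, nlat, nlon))
  (f - mean(f)) / s
}

# smooth standardized daily series (AR(1) anomaly)
smooth_series <- function(n, rho = 0.9) {
  z <- as.numeric(stats::filter(stats::rnorm(n), rho, "recursive"))
  (z - mean(z)) / stats::sd(z)
}

#' Configuration of the synthetic world
#'
#' Defaults describe the package's standard test world: a 40 x 60 cell
#' 0.25-degree fine grid nested in a 5 x 6 cell 2.0 x 2.5-degree coarse
#' grid, two years of days, 120 stations per pollutant in a clustered
#' network, and 8 contiguous countries.
#'
#' @param nlat_fine,nlon_fine Fine grid size (0.25-degree cells).
#' @param lat0,lon0 Center of the first fine cell.
#' @param start_date First day (Date or string).
#' @param n_days Number of days.
#' @param n_stations_pm,n_stations_o3 Station counts per pollutant.
#' @param n_station_clusters Centers of the clustered station point process.
#' @param station_cluster_sd SD (degrees) of station scatter around centers.
#' @param n_countries Number of contiguous synthetic countries.
#' @param fire_events_per_year Expected number of fire events per year.
#' @param fire_amp_meanlog,fire_amp_sdlog Log-normal peak plume amplitude
#'   (ug/m3) parameters for PM2.5.
#' @param fire_sigma_range Range (degrees) of plume Gaussian widths.
#' @param fire_duration_mean Mean event duration in days.
#' @param o3_fire_ratio_range Fire O3 : fire PM2.5 amplitude ratio range.
#' @param o3_negative_frac Fraction of plumes whose O3 effect is negative.
#' @param bias_amplitude Amplitude of the multiplicative coarse bias field.
#' @param chem_noise_sd SD (ug/m3) of additive noise on coarse chem fields.
#' @param obs_noise_sd SD (ug/m3) of station measurement noise.
#' @param pop_meanlog,pop_sdlog Log-normal per-cell population parameters.
#' @param ref_factor_range Country reference-total / raster-sum factor range.
#' @param seed Integer RNG seed; fixed seed implies bit-identical worlds.
#' @return An object of class `world_config`.
#' @export
world_config <- function(nlat_fine = 40, nlon_fine = 60,
                         lat0 = -4.875, lon0 = 10.125,
                         start_date = "2017-01-01", n_days = 730,
                         n_stations_pm = 120, n_stations_o3 = 120,
                         n_station_clusters = 10, station_cluster_sd = 0.8,
                         n_countries = 8,
                         fire_events_per_year = 14,
                         fire_amp_meanlog = log(40), fire_amp_sdlog = 0.5,
                         fire_sigma_range = c(0.5, 1.1),
                         fire_duration_mean = 6,
                         o3_fire_ratio_range = c(0.8, 1.6),
                         o3_negative_frac = 0.2,
                         bias_amplitude = 0.3,
                         chem_noise_sd = 1.0,
                         obs_noise_sd = 3.0,
                         pop_meanlog = 6, pop_sdlog = 1.4,
                         ref_factor_range = c(0.85, 1.3),
                         seed = 1L) {
  # coarse 2.0 x 2.5 deg cells = 8 x 10 fine cells
  if (nlat_fine %% 8 != 0 || nlon_fine %% 10 != 0)
    stop("config error: fine grid must tile into 8 x 10 cell coarse blocks")
  stopifnot(bias_amplitude >= 0, chem_noise_sd >= 0, obs_noise_sd >= 0,
            fire_events_per_year >= 0)
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "world_config")
}

fine_grid <- function(cfg)
  grid_spec(cfg$lat0, cfg$lon0, 0.25, 0.25, cfg$nlat_fine, cfg$nlon_fine)

coarse_grid <- function(cfg)
  grid_spec(cfg$lat0 + 7 * 0.25 / 2, cfg$lon0 + 9 * 0.25 / 2, 2.0, 2.5,
            cfg$nlat_fine / 8L, cfg$nlon_fine / 10L)

#' Generate a synthetic world
#'
#' See [world_config()] for the dials. The generator draws every component
#' from a named substream of one seed, so the whole world is bit-reproducible
#' and components are individually stable. It also records ground truth that
#' downstream tests consume: per-station effective measurement noise, the
#' planted fire-event table, and the exact SFAP exposure footprint
#' (person-days, people exposed, category decomposition per calendar year,
#' computed from the truth fields and the unadjusted integer population by a
#' direct per-cell scan).
#'
#' @param cfg A [world_config()].
#' @return An object of class `synthetic_world`: list with `config`, `grid`
#'   (fine), `coarse_grid`, `dates`, `covariates` (10 daily fields),
#'   `truth` (`pm_total`, `pm_fire`, `o3_total`, `o3_fire` fine fields),
#'   `chem` (same four on the coarse grid), `stations` (`pm`, `o3`),
#'   `station_noise`, `station_cells`, `population` (one raster per calendar
#'   year), `events`, and `truth_exposure`.
#' @export
make_world <- function(cfg = world_config()) {
  g <- fine_grid(cfg); gc_ <- coarse_grid(cfg)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1
  nd <- length(dates); nlat <- g$nlat; nlon <- g$nlon
  doy <- as.integer(strftime(dates, "%j"))
  lats <- grid_lats(g); lons <- grid_lons(g)

  # --- covariates -----------------------------------------------------------
  set.seed(seed_for(cfg$seed, "covariates"))
  S <- replicate(6, smooth_surface(nlat, nlon), simplify = FALSE)
  seas <- cos(2 * pi * (doy - 15) / 365.25)
  anom <- smooth_series(nd)
  mk <- function(base, spat_amp, spat, seas_amp, anom_amp, noise_sd,
                 lo = -Inf, hi = Inf, name = "cov") {
    arr <- array(0, c(nd, nlat, nlon))
    for (t in seq_len(nd))
      arr[t, , ] <- base + spat_amp * spat +
        seas_amp * seas[t] + anom_amp * anom[t] * S[[6]] +
        matrix(stats::rnorm(nlat * nlon, 0, noise_sd), nlat, nlon)
    arr <- pmin(pmax(arr, lo), hi)
    daily_field(g, dates, arr, name, "")
  }
  cov <- list(
    Tmean    = mk(24, 3.0, S[[1]], 5.0, 1.5, 0.4, name = "Tmean"),
    TV       = mk(2.5, 0.6, S[[2]], 0.5, 0.3, 0.15, lo = 0.05, name = "TV"),
    RH       = mk(65, 12, S[[3]], -8, 4, 1.5, lo = 5, hi = 100, name = "RH"),
    Wind_u   = mk(1.0, 1.2, S[[4]], 0.5, 0.8, 0.3, name = "Wind_u"),
    Wind_v   = mk(-0.5, 1.0, S[[5]], -0.4, 0.6, 0.3, name = "Wind_v"),
    Precip   = mk(3, 2.0, S[[3]], -2, 1.5, 0.8, lo = 0, name = "Precip"),
    Pressure = mk(101.3, 0.6, S[[2]], 0.4, 0.3, 0.05, name = "Pressure"),
    UV       = mk(18, 3.5, S[[1]], 6, 1.5, 0.6, lo = 0, name = "UV")
  )
  cov$Tmax <- daily_field(g, dates, cov$Tmean$values + 4 +
                            0.8 * cov$TV$values, "Tmax", "")
  cov$Tmin <- daily_field(g, dates, cov$Tmean$values - 4 -
                            0.8 * cov$TV$values, "Tmin", "")
  cov <- cov[c("Tmean", "Tmax", "Tmin", "TV", "RH", "Wind_u", "Wind_v",
               "Precip", "Pressure", "UV")]

  # --- background truth: smooth nonlinear response to the covariates -------
  set.seed(seed_for(cfg$seed, "background"))
  Spm <- smooth_surface(nlat, nlon); So3 <- smooth_surface(nlat, nlon)
  ws <- sqrt(cov$Wind_u$values^2 + cov$Wind_v$values^2)
  tdev <- cov$Tmean$values - 24
  sp_pm <- Spm
  pm_bg <- array(0, c(nd, nlat, nlon))
  o3_bg <- array(0, c(nd, nlat, nlon))
  for (t in seq_len(nd)) {
    pm_bg[t, , ] <- 14 + 5 * sp_pm + 3 * seas[t]
    o3_bg[t, , ] <- 62 + 12 * So3 + 9 * seas[t]
  }
  pm_bg <- pm_bg + 0.5 * tdev + 0.04 * tdev^2 - 0.9 * ws +
    0.07 * (80 - cov$RH$values) + 0.8 * cov$TV$values -
    1.2 * log1p(cov$Precip$values)
  pm_bg <- pmax(pm_bg, 0.5)
  o3_bg <- o3_bg + 1.1 * (cov$Tmax$values - 28) + 0.9 * cov$UV$values -
    0.035 * cov$UV$values^2 - 0.15 * cov$RH$values - 0.7 * ws
  o3_bg <- pmax(o3_bg, 5)

  # --- fire plumes ----------------------------------------------------------
  set.seed(seed_for(cfg$seed, "fires"))
  n_events <- stats::rpois(1, cfg$fire_events_per_year * nd / 365.25)
  ev <- data.frame()
  pm_fire <- array(0, c(nd, nlat, nlon))
  o3_fire <- array(0, c(nd, nlat, nlon))
  if (n_events > 0) {
    ev <- data.frame(
      event = seq_len(n_events),
      lat = stats::runif(n_events, min(lats), max(lats)),
      lon = stats::runif(n_events, min(lons), max(lons)),
      start = sample.int(nd, n_events, replace = TRUE),
      duration = 2 + stats::rpois(n_events, cfg$fire_duration_mean - 2),
      amp_pm = stats::rlnorm(n_events, cfg$fire_amp_meanlog, cfg$fire_amp_sdlog),
      sigma = stats::runif(n_events, cfg$fire_sigma_range[1],
                           cfg$fire_sigma_range[2])
    )
    ratio <- stats::runif(n_events, cfg$o3_fire_ratio_range[1],
                          cfg$o3_fire_ratio_range[2])
    neg <- stats::runif(n_events) < cfg$o3_negative_frac
    ev$amp_o3 <- ifelse(neg, -0.3 * ratio, ratio) * ev$amp_pm
    latm <- matrix(rep(lats, nlon), nlat, nlon)
    lonm <- matrix(rep(lons, each = nlat), nlat, nlon)
    for (e in seq_len(n_events)) {
      kern <- exp(-((latm - ev$lat[e])^2 + (lonm - ev$lon[e])^2) /
                    (2 * ev$sigma[e]^2))
      days <- ev$start[e]:min(nd, ev$start[e] + ev$duration[e] - 1)
      prof <- sin(pi * (seq_along(days) - 0.5) / ev$duration[e])
      for (ti in seq_along(days)) {
        pm_fire[days[ti], , ] <- pm_fire[days[ti], , ] +
          ev$amp_pm[e] * prof[ti] * kern
        o3_fire[days[ti], , ] <- o3_fire[days[ti], , ] +
          ev$amp_o3[e] * prof[ti] * kern
      }
    }
  }
  # keep the O3 fire deficit attributable: |fire| <= total requires
  # fire >= -background/2
  o3_fire <- pmax(o3_fire, -0.45 * o3_bg)
  truth <- list(
    pm_total = daily_field(g, dates, pm_bg + pm_fire, "pm25_truth_total",
                           nonneg = TRUE),
    pm_fire  = daily_field(g, dates, pm_fire, "pm25_truth_fire", nonneg = TRUE),
    o3_total = daily_field(g, dates, o3_bg + o3_fire, "o3_truth_total",
                           nonneg = TRUE),
    o3_fire  = daily_field(g, dates, o3_fire, "o3_truth_fire")
  )

  # --- coarse chem fields: biased, noisy block means ------------------------
  set.seed(seed_for(cfg$seed, "chem"))
  bias <- 1 + cfg$bias_amplitude * smooth_surface(gc_$nlat, gc_$nlon)
  bias <- pmax(bias, 0.2)
  # fire fields get noise only where a fire signal exists, so a fire-free
  # world yields an exactly-zero chem fire field (and fire fraction)
  mk_chem <- function(fine_field, name, noise_scale = 1, fire = FALSE) {
    bm <- block_mean(fine_field, gc_)
    arr <- bm$values
    for (t in seq_len(nd)) {
      eps <- matrix(stats::rnorm(gc_$nlat * gc_$nlon, 0,
                                 cfg$chem_noise_sd * noise_scale),
                    gc_$nlat, gc_$nlon)
      if (fire) eps <- eps * (arr[t, , ] != 0)
      arr[t, , ] <- arr[t, , ] * bias + eps
    }
    daily_field(gc_, dates, arr, name, "ug/m3")
  }
  chem <- list(
    pm_total = mk_chem(truth$pm_total, "pm25_chem_total"),
    pm_fire  = mk_chem(truth$pm_fire, "pm25_chem_fire", 0.5, fire = TRUE),
    o3_total = mk_chem(truth$o3_total, "o3_chem_total"),
    o3_fire  = mk_chem(truth$o3_fire, "o3_chem_fire", 0.5, fire = TRUE)
  )
  # physical consistency of the paired simulations: totals non-negative,
  # PM fire share within [0, total], O3 fire magnitude within total
  chem$pm_total$values <- pmax(chem$pm_total$values, 0)
  chem$o3_total$values <- pmax(chem$o3_total$values, 0)
  chem$pm_fire$values <- pmin(pmax(chem$pm_fire$values, 0),
                              chem$pm_total$values)
  chem$o3_fire$values <- pmin(pmax(chem$o3_fire$values,
                                   -chem$o3_total$values),
                              chem$o3_total$values)

  # --- clustered station networks ------------------------------------------
  lat_rng <- range(lats); lon_rng <- range(lons)
  place_stations <- function(n, prefix, stream) {
    set.seed(seed_for(cfg$seed, stream))
    centers <- cbind(stats::runif(cfg$n_station_clusters, lat_rng[1], lat_rng[2]),
                     stats::runif(cfg$n_station_clusters, lon_rng[1], lon_rng[2]))
    out <- matrix(NA_real_, n, 2)
    filled <- 0
    while (filled < n) {
      ci <- sample.int(cfg$n_station_clusters, 1)
      p <- centers[ci, ] + stats::rnorm(2, 0, cfg$station_cluster_sd)
      if (p[1] >= lat_rng[1] && p[1] <= lat_rng[2] &&
          p[2] >= lon_rng[1] && p[2] <= lon_rng[2]) {
        filled <- filled + 1
        out[filled, ] <- p
      }
    }
    data.frame(station_id = sprintf("%s%03d", prefix, seq_len(n)),
               lat = out[, 1], lon = out[, 2], stringsAsFactors = FALSE)
  }
  obs_from_truth <- function(locs, truth_field, stream) {
    set.seed(seed_for(cfg$seed, stream))
    n <- nrow(locs)
    cells <- t(vapply(seq_len(n),
                      function(s) locate_cell(g, locs$lon[s], locs$lat[s]),
                      integer(2)))
    obs <- matrix(NA_real_, nd, n)
    noise <- matrix(stats::rnorm(nd * n, 0, cfg$obs_noise_sd), nd, n)
    for (s in seq_len(n)) {
      tr <- truth_field$values[, cells[s, 1], cells[s, 2]]
      o <- pmax(tr + noise[, s], 0)   # physical floor
      noise[, s] <- o - tr            # record effective noise
      obs[, s] <- o
    }
    list(obs = obs, noise = noise, cells = cells)
  }
  loc_pm <- place_stations(cfg$n_stations_pm, "PM", "stations_pm")
  loc_o3 <- place_stations(cfg$n_stations_o3, "O3", "stations_o3")
  sp <- obs_from_truth(loc_pm, truth$pm_total, "obs_pm")
  so <- obs_from_truth(loc_o3, truth$o3_total, "obs_o3")
  mk_series <- function(locs, obs, pollutant) {
    n <- nrow(locs)
    station_series(rep(locs$station_id, each = nd),
                   rep(locs$lon, each = nd), rep(locs$lat, each = nd),
                   rep(dates, n), pollutant, as.vector(obs))
  }
  stations <- list(pm = mk_series(loc_pm, sp$obs, "pm25"),
                   o3 = mk_series(loc_o3, so$obs, "o3"))

  # --- population raster and synthetic countries ----------------------------
  set.seed(seed_for(cfg$seed, "population"))
  ctr <- cbind(stats::runif(cfg$n_countries, lat_rng[1], lat_rng[2]),
               stats::runif(cfg$n_countries, lon_rng[1], lon_rng[2]))
  latm <- matrix(rep(lats, nlon), nlat, nlon)
  lonm <- matrix(rep(lons, each = nlat), nlat, nlon)
  country <- matrix(0L, nlat, nlon)
  for (i in seq_len(nlat)) for (j in seq_len(nlon))
    country[i, j] <- which.min((latm[i, j] - ctr[, 1])^2 +
                                 (lonm[i, j] - ctr[, 2])^2)
  counts0 <- matrix(round(stats::rlnorm(nlat * nlon, cfg$pop_meanlog,
                                        cfg$pop_sdlog)), nlat, nlon)
  factors <- stats::runif(cfg$n_countries, cfg$ref_factor_range[1],
                          cfg$ref_factor_range[2])
  factors[abs(factors - 1) < 0.02] <- 1.05
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  growth <- stats::runif(length(years), 1.0, 1.03)
  population <- list()
  for (yi in seq_along(years)) {
    counts <- round(counts0 * prod(growth[seq_len(yi)]) / growth[1])
    sums <- tapply(as.vector(counts), as.vector(country), sum)
    ref <- sums * factors[as.integer(names(sums))]
    names(ref) <- names(sums)
    population[[as.character(years[yi])]] <-
      population_raster(g, years[yi], counts, country, ref)
  }

  # --- exact SFAP footprint of the planted truth (independent direct scan) --
  truth_exposure <- exposure_footprint_scan(truth, population, dates)

  structure(list(config = cfg, grid = g, coarse_grid = gc_, dates = dates,
                 covariates = cov, truth = truth, chem = chem,
                 stations = stations,
                 station_noise = list(pm = sp$noise, o3 = so$noise),
                 station_cells = list(pm = sp$cells, o3 = so$cells),
                 population = population, events = ev, bias = bias,
                 truth_exposure = truth_exposure),
            class = "synthetic_world")
}

# Direct per-cell scan of the truth fields against the SFAP definition
# (PM2.5 > 15 with fire share >= 0.5, or MDA8 O3 > 100 with fire share
# >= 0.5), kept deliberately loop-structured and separate from the exposure
# module so it can serve as that module's known answer.
exposure_footprint_scan <- function(truth, population, dates,
                                    pm_thr = 15, o3_thr = 100, frac = 0.5) {
  yrs <- as.integer(format(dates, "%Y"))
  out <- data.frame()
  for (ynm in names(population)) {
    pop <- population[[ynm]]
    sel <- which(yrs == as.integer(ynm))
    pd <- pd_pm <- pd_o3 <- pd_both <- 0
    exposed_pop <- 0
    total_pop <- sum(pop$counts)
    for (i in seq_len(pop$grid$nlat)) for (j in seq_len(pop$grid$nlon)) {
      pt <- truth$pm_total$values[sel, i, j]
      pf <- truth$pm_fire$values[sel, i, j]
      ot <- truth$o3_total$values[sel, i, j]
      of <- truth$o3_fire$values[sel, i, j]
      pm_hit <- !is.na(pt) & !is.na(pf) & pt > pm_thr & pf >= frac * pt & pf >= 0
      o3_hit <- !is.na(ot) & !is.na(of) & ot > o3_thr & of >= frac * ot & of >= 0
      n_pm <- sum(pm_hit & !o3_hit); n_o3 <- sum(o3_hit & !pm_hit)
      n_both <- sum(pm_hit & o3_hit)
      cpop <- pop$counts[i, j]
      pd_pm <- pd_pm + n_pm * cpop
      pd_o3 <- pd_o3 + n_o3 * cpop
      pd_both <- pd_both + n_both * cpop
      if (n_pm + n_o3 + n_both > 0) exposed_pop <- exposed_pop + cpop
    }
    pd <- pd_pm + pd_o3 + pd_both
    out <- rbind(out, data.frame(
      year = as.integer(ynm), person_days = pd,
      person_days_pm_only = pd_pm, person_days_o3_only = pd_o3,
      person_days_both = pd_both,
      people_exposed = exposed_pop, total_population = total_pop,
      days_per_person = pd / total_pop))
  }
  out
}

#' Truth series at a station's grid cell
#'
#' @param world A [make_world()] result.
#' @param station_id Station identifier.
#' @return Numeric vector of the truth total concentration (the station's
#'   pollutant) over the world's dates.
#' @export
station_truth <- function(world, station_id) {
  for (p in c("pm", "o3")) {
    locs <- station_locations(world$stations[[p]])
    k <- match(station_id, locs$station_id)
    if (!is.na(k)) {
      cell <- locate_cell(world$grid, locs$lon[k], locs$lat[k])
      fld <- if (p == "pm") world$truth$pm_total else world$truth$o3_total
      return(fld$values[, cell[1], cell[2]])
    }
  }
  stop("station_truth: unknown station id '", station_id, "'")
}

#' Write a synthetic world's files to a directory
#'
#' Emits the same formats the pipeline reads: gridded text fields for the
#' coarse chem fields and covariates, station CSVs, and a population CSV
#' per year (`lat_index, lon_index, count, country_id` plus a reference
#' totals CSV).
#'
#' @param world A [make_world()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wf <- function(field, name) {
    p <- file.path(dir, paste0(name, ".grid.txt"))
    write_field(field, p); paths <<- c(paths, p)
  }
  for (nm in names(world$chem)) wf(world$chem[[nm]], paste0("chem_", nm))
  for (nm in names(world$covariates)) wf(world$covariates[[nm]], paste0("met_", nm))
  for (p in c("pm", "o3")) {
    fp <- file.path(dir, paste0("stations_", p, ".csv"))
    write_stations(world$stations[[p]], fp); paths <- c(paths, fp)
  }
  for (ynm in names(world$population)) {
    pop <- world$population[[ynm]]
    fp <- file.path(dir, paste0("population_", ynm, ".csv"))
    df <- expand.grid(ilat = seq_len(pop$grid$nlat),
                      ilon = seq_len(pop$grid$nlon))
    df$count <- pop$counts[cbind(df$ilat, df$ilon)]
    df$country_id <- pop$country_id[cbind(df$ilat, df$ilon)]
    utils::write.csv(df, fp, row.names = FALSE)
    rf <- file.path(dir, paste0("reference_totals_", ynm, ".csv"))
    utils::write.csv(data.frame(country_id = names(pop$ref_totals),
                                reference_total = as.numeric(pop$ref_totals)),
                     rf, row.names = FALSE)
    paths <- c(paths, fp, rf)
  }
  invisible(paths)
}
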