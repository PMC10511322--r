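make_small_setup <- function(n_days = 10, seed = 2) {
  g <- grid_spec(0.125, 0.125, 0.25, 0.25, 4, 4)
  dates <- as.Date("2018-01-01") + seq_len(n_days) - 1
  set.seed(seed)
  mkf <- function(name) daily_field(
    g, dates, array(runif(n_days * 16, 1, 30), c(n_days, 4, 4)), name)
  cov <- stats::setNames(
    lapply(c("Tmean", "Tmax", "Tmin", "TV", "RH", "Wind_u", "Wind_v",
             "Precip", "Pressure", "UV"), mkf),
    c("Tmean", "Tmax", "Tmin", "TV", "RH", "Wind_u", "Wind_v",
      "Precip", "Pressure", "UV"))
  chem <- mkf("pm25_chem_total")
  st <- station_series(rep(c("A", "B"), each = n_days),
                       rep(c(0.2, 0.7), each = n_days),
                       rep(c(0.2, 0.6), each = n_days),
                       rep(dates, 2), "pm25", runif(2 * n_days, 5, 40))
  list(grid = g, dates = dates, cov = cov, chem = chem, st = st)
}

test_that("training assembly produces one complete row per station-day", {
  s <- make_small_setup()
  tab <- assemble_training(s$st, s$chem, s$cov)
  expect_equal(nrow(tab), 20)
  expect_true(all(firesmoke:::CALIBRATION_FEATURES %in% names(tab)))
  expect_equal(length(firesmoke:::CALIBRATION_FEATURES), 17)
  expect_true(all(tab$DOW %in% 1:7) && all(tab$Month %in% 1:12))
  # one missing covariate on one station-day drops exactly that row
  s$cov$RH$values[3, 1, 1] <- NA   # station A's cell
  tab2 <- assemble_training(s$st, s$chem, s$cov)
  expect_equal(nrow(tab2), 19)
  # station outside the grid is excluded with a warning
  bad <- station_series("Z", 50, 50, s$dates[1], "pm25", 10)
  both <- rbind(as.data.frame(s$st), as.data.frame(bad))
  class(both) <- class(s$st)
  expect_warning(tab3 <- assemble_training(both, s$chem, s$cov), "outside")
  expect_equal(sort(unique(tab3$station_id)), c("A", "B"))
})

test_that("calendar predictors handle leap days and Monday-first DOW", {
  s <- make_small_setup()
  # 2004-02-29 is a Sunday: DOY 60, DOW 7
  g <- s$grid
  dates <- as.Date("2004-02-28") + 0:2
  chem <- daily_field(g, dates, array(5, c(3, 4, 4)))
  cov <- lapply(s$cov, function(f) daily_field(g, dates, f$values[1:3, , ],
                                               f$variable))
  st <- station_series(rep("A", 3), 0.2, 0.2, dates, "pm25", c(9, 9, 9))
  tab <- assemble_training(st, chem, cov)
  row <- tab[tab$date == as.Date("2004-02-29"), ]
  expect_equal(row$DOY, 60)
  expect_equal(row$Year, 2004)
  expect_equal(row$DOW, 7)
  expect_equal(tab$DOW[tab$date == as.Date("2004-03-01")], 1)
})

test_that("calibration fitting is seeded-deterministic and learnable", {
  w <- make_world(world_config(nlat_fine = 8, nlon_fine = 10, n_days = 90,
                               n_stations_pm = 20, n_stations_o3 = 5,
                               n_station_clusters = 3, n_countries = 2,
                               obs_noise_sd = 0, bias_amplitude = 0,
                               chem_noise_sd = 0, seed = 31))
  fine <- idw_downscale(w$chem$pm_total, w$grid)
  tab <- assemble_training(w$stations$pm, fine, w$covariates)
  m1 <- fit_calibration(tab, num_trees = 200, mtry = 5, seed = 8)
  m2 <- fit_calibration(tab, num_trees = 200, mtry = 5, seed = 8)
  p1 <- predict(m1, tab); p2 <- predict(m2, tab)
  expect_identical(p1, p2)
  # noiseless observations are a smooth function of the predictors:
  # the forest must capture almost all in-sample variance
  r2 <- 1 - sum((p1 - tab$obs)^2) / sum((tab$obs - mean(tab$obs))^2)
  expect_gt(r2, 0.95)
  expect_true(all(p1 >= 0))
})

test_that("a shuffled response carries no out-of-fold signal", {
  w <- make_world(world_config(nlat_fine = 8, nlon_fine = 10, n_days = 60,
                               n_stations_pm = 15, n_stations_o3 = 5,
                               n_station_clusters = 3, n_countries = 2,
                               seed = 32))
  fine <- idw_downscale(w$chem$pm_total, w$grid)
  tab <- assemble_training(w$stations$pm, fine, w$covariates)
  set.seed(1)
  tab$obs <- sample(tab$obs)
  part <- make_partition(tab, "row_kfold", k = 5, seed = 2)
  cv <- cross_validate(tab, part, rf_fit_fn(num_trees = 100, seed = 3))
  expect_lt(cv$r2, 0.1)
})

test_that("gridded prediction propagates missing predictors and stays in range", {
  s <- make_small_setup(n_days = 30)
  tab <- assemble_training(s$st, s$chem, s$cov)
  m <- fit_calibration(tab, num_trees = 100, mtry = 5, seed = 4)
  s$cov$UV$values[2, 3, 3] <- NA
  est <- predict_total(m, s$chem, s$cov)
  expect_true(is.na(est$values[2, 3, 3]))
  ok <- !is.na(est$values)
  expect_true(all(est$values[ok] >= m$response_range[1] - 1e-9))
  expect_true(all(est$values[ok] <= m$response_range[2] + 1e-9))
  # feature mismatch is a contract error
  expect_error(predict(m, data.frame(chem_total = 1)), "feature mismatch")
})

test_that("fire fraction follows the stated conventions", {
  g <- grid_spec(0, 0, 1, 1, 1, 2)
  d <- as.Date("2018-01-01")
  f <- function(v) daily_field(g, d, array(v, c(1, 1, 2)))
  expect_equal(as.vector(fire_fraction(f(c(3, 5)), f(c(12, 5)))$values),
               c(0.25, 1))
  expect_equal(as.vector(fire_fraction(f(c(0, 2)), f(c(0, 0)))$values),
               c(0, 0))   # zero total -> fraction 0 by rule
  expect_message(fr <- fire_fraction(f(c(30, 1)), f(c(10, 2))), "clipped")
  expect_equal(as.vector(fr$values), c(1, 0.5))
  expect_equal(attr(fr, "n_clipped"), 1)
  g2 <- grid_spec(5, 5, 1, 1, 1, 2)
  expect_error(fire_fraction(daily_field(g2, d, array(1, c(1, 1, 2))),
                             f(c(1, 1))), "misaligned")
})

test_that("ratio scaling preserves the chem fire share exactly", {
  g <- grid_spec(0, 0, 1, 1, 3, 3)
  dates <- as.Date("2018-01-01") + 0:4
  set.seed(6)
  tot <- daily_field(g, dates, array(runif(45, 1, 40), c(5, 3, 3)))
  fire <- daily_field(g, dates, tot$values * runif(45, 0, 1))
  frac <- fire_fraction(fire, tot)
  est_total <- daily_field(g, dates, array(runif(45, 1, 50), c(5, 3, 3)))
  est_fire <- scale_fire(est_total, frac)
  # elementwise loop oracle
  for (i in sample(45, 10))
    expect_equal(est_fire$values[i], est_total$values[i] * frac$values[i],
                 tolerance = 1e-15)
  expect_true(all(abs(est_fire$values) <= est_total$values + 1e-12))
  # the ratio-preservation identity wherever est_total > 0
  pos <- est_total$values > 0
  expect_equal((est_fire$values / est_total$values)[pos],
               frac$values[pos], tolerance = 1e-12)
})

test_that("mtry tuning selects from the documented grid by CV RMSE", {
  s <- make_small_setup(n_days = 40, seed = 7)
  tab <- assemble_training(s$st, s$chem, s$cov)
  m <- fit_calibration(tab, num_trees = 60, mtry = NULL, cv_folds = 3,
                       seed = 13)
  expect_true(m$hyperparams$mtry %in% c(3, 5, 7, 9))
  expect_named(m$cv_rmse, c("3", "5", "7", "9"))
  expect_equal(m$hyperparams$mtry,
               as.numeric(names(which.min(m$cv_rmse))))
  # tuning is deterministic under the seed
  m2 <- fit_calibration(tab, num_trees = 60, mtry = NULL, cv_folds = 3,
                        seed = 13)
  expect_identical(m$cv_rmse, m2$cv_rmse)
})

test_that("calibration artifacts reload and predict identically", {
  s <- make_small_setup(n_days = 30)
  tab <- assemble_training(s$st, s$chem, s$cov)
  m <- fit_calibration(tab, num_trees = 50, mtry = 3, seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  save_calibration(m, path)
  m2 <- load_calibration(path)
  expect_identical(predict(m2, tab), predict(m, tab))
})
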