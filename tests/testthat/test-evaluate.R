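fake_table <- function(n_stations = 5, n_days = 8, seed = 20) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_stations))
  df <- expand.grid(station_id = ids,
                    date = as.Date("2018-01-01") + seq_len(n_days) - 1,
                    stringsAsFactors = FALSE)
  df$x <- rnorm(nrow(df))
  df$obs <- 3 + 2 * df$x + rnorm(nrow(df), 0, 0.3)
  df
}

test_that("partitions respect scheme, balance and determinism", {
  tab <- fake_table(10, 10)
  p <- make_partition(tab, "row_kfold", k = 10, seed = 1)
  expect_equal(as.vector(table(p$fold)), rep(10, 10))
  p2 <- make_partition(tab, "row_kfold", k = 10, seed = 1)
  expect_identical(p$fold, p2$fold)
  ps <- make_partition(tab, "station_kfold", k = 5, seed = 1)
  # no station split across folds
  per_station <- tapply(ps$fold, tab$station_id, function(f) length(unique(f)))
  expect_true(all(per_station == 1))
  # station fold sizes within one station of equal
  sizes <- table(tapply(ps$fold, tab$station_id, unique))
  expect_lte(diff(range(sizes)), 1)
  expect_error(make_partition(tab, "station_kfold", k = 11), "exceeds")
})

test_that("cross-validation metrics behave at the two extremes", {
  tab <- fake_table()
  part <- make_partition(tab, "row_kfold", k = 4, seed = 2)
  copy_fit <- function(train) function(newdata) newdata$obs
  cv <- cross_validate(tab, part, copy_fit)
  expect_equal(cv$r2, 1)
  expect_equal(cv$rmse, 0)
  mean_fit <- function(train) { m <- mean(train$obs); function(newdata) rep(m, nrow(newdata)) }
  cv0 <- cross_validate(tab, part, mean_fit)
  expect_lte(cv0$r2, 0.001)
})

test_that("cross-validation equals a hand-rolled out-of-fold loop", {
  tab <- fake_table(4, 6, seed = 21)
  part <- make_partition(tab, "station_kfold", k = 4, seed = 3)
  lm_fit <- function(train) {
    fit <- stats::lm(obs ~ x, data = train)
    function(newdata) unname(stats::predict(fit, newdata))
  }
  cv <- cross_validate(tab, part, lm_fit)
  # brute-force oracle
  pred <- rep(NA_real_, nrow(tab))
  for (f in unique(part$fold)) {
    fit <- stats::lm(obs ~ x, data = tab[part$fold != f, ])
    pred[part$fold == f] <- stats::predict(fit, tab[part$fold == f, ])
  }
  expect_equal(cv$predictions$pred, unname(pred), tolerance = 1e-12)
  expect_equal(cv$r2, 1 - sum((tab$obs - pred)^2) /
                 sum((tab$obs - mean(tab$obs))^2), tolerance = 1e-12)
  expect_equal(cv$rmse, sqrt(mean((tab$obs - pred)^2)), tolerance = 1e-12)
  # every out-of-fold prediction comes from a model that never saw the station
  expect_true(all(tapply(cv$predictions$fold, cv$predictions$station_id,
                         function(f) length(unique(f))) == 1))
})

test_that("k-means clustering recovers separated blobs and degenerate k", {
  set.seed(4)
  locs <- data.frame(
    station_id = sprintf("S%02d", 1:30),
    lon = c(rnorm(15, 0, 0.3), rnorm(15, 20, 0.3)),
    lat = c(rnorm(15, 0, 0.3), rnorm(15, 10, 0.3)))
  cl <- kmeans_station_clusters(locs, k = 2, seed = 5)
  expect_equal(length(unique(cl[1:15])), 1)
  expect_equal(length(unique(cl[16:30])), 1)
  expect_false(cl[1] == cl[16])
  # k = number of stations -> zero within-group SS
  cln <- kmeans_station_clusters(locs, k = 30, seed = 5)
  expect_equal(attr(cln, "tot_withinss"), 0, tolerance = 1e-9)
  # within-SS no worse than random labelings
  cl3 <- kmeans_station_clusters(locs, k = 3, seed = 5)
  wss <- function(lab) {
    sum(vapply(unique(lab), function(l) {
      m <- locs[lab == l, c("lon", "lat")]
      sum(scale(m, scale = FALSE)^2)
    }, 0))
  }
  set.seed(6)
  rand_wss <- replicate(100, wss(sample(1:3, 30, replace = TRUE)))
  expect_lte(attr(cl3, "tot_withinss"), min(rand_wss))
  # elbow rule picks an interior k on a 3-blob configuration
  locs3 <- data.frame(station_id = sprintf("T%02d", 1:30),
                      lon = c(rnorm(10, 0, 0.2), rnorm(10, 10, 0.2),
                              rnorm(10, 20, 0.2)),
                      lat = c(rnorm(10, 0, 0.2), rnorm(10, 10, 0.2),
                              rnorm(10, 0, 0.2)))
  cl_auto <- kmeans_station_clusters(locs3, k = 2:6, seed = 7)
  expect_equal(attr(cl_auto, "k"), 3)
})

test_that("leave-one-cluster-out reduces to station k-fold on equal labels", {
  tab <- fake_table(6, 5, seed = 22)
  part <- make_partition(tab, "station_kfold", k = 3, seed = 8)
  fold_by_station <- tapply(part$fold, tab$station_id, unique)
  clusters <- stats::setNames(as.integer(fold_by_station),
                              names(fold_by_station))
  lm_fit <- function(train) {
    fit <- stats::lm(obs ~ x, data = train)
    function(newdata) unname(stats::predict(fit, newdata))
  }
  ccv <- cluster_loocv(tab, clusters, lm_fit)
  scv <- cross_validate(tab, part, lm_fit)
  expect_equal(sort(ccv$predictions$pred), sort(scv$predictions$pred),
               tolerance = 1e-12)
  expect_equal(ccv$r2, scv$r2, tolerance = 1e-12)
  # two clusters: hand computation with two fits
  cl2 <- stats::setNames(rep(1:2, each = 3), sort(unique(tab$station_id)))
  ccv2 <- cluster_loocv(tab, cl2, lm_fit)
  in1 <- tab$station_id %in% names(cl2)[cl2 == 1]
  f1 <- stats::lm(obs ~ x, data = tab[!in1, ]); f2 <- stats::lm(obs ~ x, data = tab[in1, ])
  pred <- ifelse(in1, stats::predict(f1, tab), stats::predict(f2, tab))
  expect_equal(ccv2$r2, 1 - sum((tab$obs - pred)^2) /
                 sum((tab$obs - mean(tab$obs))^2), tolerance = 1e-12)
})

test_that("within-R2 equals the dummy-variable fixed-effects oracle", {
  expect_equal(within_r2(1:10, 1:10, rep(1:2, 5), rep(1:5, 2)), 1)
  set.seed(9)
  for (rep in 1:5) {
    n_i <- sample(10:50, 1); n_t <- sample(4:10, 1)
    id <- rep(seq_len(n_i), each = n_t)
    tt <- rep(seq_len(n_t), n_i)
    est <- rnorm(n_i * n_t) + 0.5 * rnorm(n_i)[id] + 0.3 * rnorm(n_t)[tt]
    obs <- 1 + 0.8 * est + rnorm(n_i)[id] + rnorm(n_t)[tt] +
      rnorm(n_i * n_t, 0, 0.7)
    got <- within_r2(obs, est, id, tt)
    # oracle: partial R2 of est in the dummy-variable OLS
    rss_full <- sum(resid(stats::lm(obs ~ est + factor(id) + factor(tt)))^2)
    rss_fe <- sum(resid(stats::lm(obs ~ factor(id) + factor(tt)))^2)
    expect_equal(got, (rss_fe - rss_full) / rss_fe, tolerance = 1e-8)
  }
  # an estimate absorbed by the fixed effects is undefined
  id <- rep(1:4, each = 5); tt <- rep(1:5, 4)
  expect_warning(r <- within_r2(rnorm(20), as.numeric(id), id, tt), "absorbed")
  expect_true(is.nan(r))
})

test_that("station-specific R2 summaries match direct computation", {
  set.seed(10)
  pred_tab <- do.call(rbind, lapply(1:5, function(s) {
    obs <- rnorm(40, 10, 3)
    noise_sd <- c(0.1, 0.5, 1, 2, 4)[s]
    data.frame(station_id = sprintf("S%d", s),
               date = as.Date("2018-01-01") + 1:40,
               fold = 1L, obs = obs, pred = obs + rnorm(40, 0, noise_sd))
  }))
  sr <- station_r2(pred_tab, min_obs = 30)
  direct <- vapply(split(pred_tab, pred_tab$station_id), function(d)
    1 - sum((d$obs - d$pred)^2) / sum((d$obs - mean(d$obs))^2), 0)
  expect_equal(sort(sr$per_station$r2), sort(unname(direct)))
  expect_equal(sr$median, median(direct))
  expect_equal(sr$q10, unname(quantile(direct, 0.1)))
  # perfect predictions give R2 = 1; mean prediction gives R2 = 0
  perfect <- transform(pred_tab, pred = obs)
  expect_equal(station_r2(perfect, 30)$median, 1)
  one <- subset(pred_tab, station_id == "S1")
  one$pred <- mean(one$obs)
  expect_equal(station_r2(one, 30)$per_station$r2, 0)
  # stations below the minimum are excluded and counted
  short <- station_r2(pred_tab[pred_tab$station_id != "S1" |
                                 seq_len(nrow(pred_tab)) <= 10, ], 30)
  expect_equal(short$n_excluded, 1)
})

test_that("smoke PM2.5 uses the 3-year month-median background", {
  # station A: non-smoke Januaries of 2017-2019 hold values {8, 10, 12}
  dates <- as.Date(c("2017-01-05", "2018-01-03", "2019-01-07", "2018-01-10",
                     "2018-06-10"))
  st <- station_series(rep("A", 5), 0, 0, dates, "pm25",
                       c(8, 10, 12, 40, 20))
  smoke <- data.frame(station_id = "A", date = as.Date("2018-01-10"))
  out <- observed_smoke_pm(st, smoke)
  expect_equal(out$smoke_pm25[out$date == as.Date("2018-01-10")], 40 - 10)
  expect_equal(out$background[out$date == as.Date("2018-01-10")], 10)
  # non-smoke days are identically zero
  expect_true(all(out$smoke_pm25[!out$smoke_day] == 0))
  # observation below background floors at zero
  st2 <- station_series(rep("A", 4), 0, 0, dates[1:4], "pm25", c(8, 10, 12, 9))
  out2 <- observed_smoke_pm(st2, smoke)
  expect_equal(out2$smoke_pm25[out2$date == as.Date("2018-01-10")], 0)
  # translation equivariance: +c everywhere leaves smoke PM unchanged
  st3 <- station_series(rep("A", 5), 0, 0, dates, "pm25",
                        c(8, 10, 12, 40, 20) + 5)
  out3 <- observed_smoke_pm(st3, smoke)
  expect_equal(out3$smoke_pm25, out$smoke_pm25)
  # no non-smoke observations in the window -> NA
  st4 <- station_series("A", 0, 0, as.Date("2018-01-10"), "pm25", 40)
  out4 <- observed_smoke_pm(st4, smoke)
  expect_true(is.na(out4$smoke_pm25))
})

test_that("the most affected station maximizes the event increase", {
  dates <- as.Date("2020-01-01") + 0:19
  mk <- function(id, base, bump)
    station_series(rep(id, 20), 0.1 * match(id, c("A", "B", "C")), 0,
                   dates, "pm25", c(rep(base, 10), rep(base + bump, 10)))
  st <- do.call(rbind, list(mk("A", 10, 2), mk("B", 12, 15), mk("C", 9, 7)))
  class(st) <- c("station_series", "data.frame")
  pre <- dates[1:10]; ev <- dates[11:20]
  res <- most_affected_station(st, 0, 0, ev, pre, radius_km = 500)
  expect_equal(res$station_id, "B")
  expect_equal(res$increase, 15)
  # brute-force scan agreement
  expect_equal(res$stations$increase[order(res$stations$station_id)],
               c(2, 15, 7))
  # tie breaks to the smaller station id
  st2 <- rbind(mk("A", 10, 10), mk("B", 12, 10))
  class(st2) <- c("station_series", "data.frame")
  expect_equal(most_affected_station(st2, 0, 0, ev, pre, 500)$station_id, "A")
  # no station in radius with data -> selection error
  expect_error(most_affected_station(st, 50, 50, ev, pre, radius_km = 10),
               "selection error")
})
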