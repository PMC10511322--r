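two_cell_flags <- function() {
  # cell (1,1): flagged day 1 and 2; cell (1,2): flagged day 2 only
  g <- grid_spec(0, 0, 1, 1, 1, 2)
  dates <- as.Date("2018-01-01") + 0:1
  f <- function(v) daily_field(g, dates, array(v, c(2, 1, 2)))
  pm_total <- f(c(20, 20, 10, 20)); pm_fire <- f(c(12, 12, 1, 12))
  o3_total <- f(60); o3_fire <- f(0)
  flag_sfap(pm_total, pm_fire, o3_total, o3_fire)
}

two_cell_pop <- function(counts = c(100, 50)) {
  g <- grid_spec(0, 0, 1, 1, 1, 2)
  population_raster(g, 2018, matrix(counts, 1, 2), matrix(1L, 1, 2),
                    c("1" = sum(counts)))
}

test_that("SFAP flags implement the joint guideline/share criteria", {
  g <- grid_spec(0, 0, 1, 1, 1, 1)
  d <- as.Date("2018-01-01")
  f <- function(v) daily_field(g, d, array(v, c(1, 1, 1)))
  cat_of <- function(pt, pf, ot, of)
    flag_sfap(f(pt), f(pf), f(ot), f(of))$category[1, 1, 1]
  expect_equal(cat_of(20, 12, 60, 0), 1L)    # pm_only: 12/20 = 0.6 >= 0.5
  expect_equal(cat_of(20, 5, 60, 0), 0L)     # share 0.25 fails
  expect_equal(cat_of(15, 10, 60, 0), 0L)    # "exceeds" is strict
  expect_equal(cat_of(10, 9, 120, 70), 2L)   # o3_only
  expect_equal(cat_of(20, 12, 120, 70), 3L)  # both
  expect_equal(cat_of(20, 12, 120, 40), 1L)  # o3 share fails
  # negative fire values never qualify
  expect_equal(cat_of(20, 12, 120, -70), 1L)
  # missing values give category none and are counted
  fl <- flag_sfap(f(NA), f(12), f(120), f(70))
  expect_equal(fl$category[1, 1, 1], 2L)  # o3 criterion still evaluable
  expect_equal(fl$n_missing, 1)
})

test_that("person-day bookkeeping matches the worked two-cell example", {
  flags <- two_cell_flags()
  pop <- two_cell_pop()
  expect_equal(person_days(flags, pop), 250)  # 100 (day1) + 150 (day2)
  expect_equal(days_per_person(250, pop), 250 / 150)
  expect_equal(people_exposed(flags, pop), 150)
  # identity person_days = days_per_person * total population
  expect_equal(days_per_person(250, pop) * sum(pop$counts), 250,
               tolerance = 1e-9)
  # no flags -> zeros
  g <- flags$grid
  none <- flag_sfap(daily_field(g, flags$dates, array(1, c(2, 1, 2))),
                    daily_field(g, flags$dates, array(0, c(2, 1, 2))),
                    daily_field(g, flags$dates, array(1, c(2, 1, 2))),
                    daily_field(g, flags$dates, array(0, c(2, 1, 2))))
  expect_equal(person_days(none, pop), 0)
  expect_equal(people_exposed(none, pop), 0)
  expect_error(days_per_person(0, two_cell_pop(c(0, 0))), "zero")
})

test_that("exposure metrics equal triple-loop oracles on random worlds", {
  set.seed(14)
  g <- grid_spec(0, 0, 1, 1, 4, 5)
  dates <- as.Date("2018-01-01") + 0:9
  f <- function(v) daily_field(g, dates, array(v, c(10, 4, 5)))
  pm_total <- f(runif(200, 0, 40)); pm_fire <- f(runif(200, 0, 25))
  pm_fire$values <- pmin(pm_fire$values, pm_total$values)
  o3_total <- f(runif(200, 40, 140)); o3_fire <- f(runif(200, -20, 90))
  o3_fire$values <- pmin(o3_fire$values, o3_total$values)
  flags <- flag_sfap(pm_total, pm_fire, o3_total, o3_fire)
  counts <- matrix(rpois(20, 80), 4, 5)
  pop <- population_raster(g, 2018, counts, matrix(1L, 4, 5),
                           c("1" = sum(counts)))
  pd_oracle <- 0; exposed_oracle <- 0
  for (i in 1:4) for (j in 1:5) {
    hit <- FALSE
    for (t in 1:10) {
      pm_ok <- pm_total$values[t, i, j] > 15 &&
        pm_fire$values[t, i, j] >= 0.5 * pm_total$values[t, i, j] &&
        pm_fire$values[t, i, j] >= 0
      o3_ok <- o3_total$values[t, i, j] > 100 &&
        o3_fire$values[t, i, j] >= 0.5 * o3_total$values[t, i, j] &&
        o3_fire$values[t, i, j] >= 0
      if (pm_ok || o3_ok) { pd_oracle <- pd_oracle + counts[i, j]; hit <- TRUE }
    }
    if (hit) exposed_oracle <- exposed_oracle + counts[i, j]
  }
  expect_equal(person_days(flags, pop), pd_oracle)
  expect_equal(people_exposed(flags, pop), exposed_oracle)
  expect_lte(people_exposed(flags, pop), sum(pop$counts))
  # category person-days partition the total exactly
  expect_equal(person_days(flags, pop),
               person_days(flags, pop, "pm_only") +
                 person_days(flags, pop, "o3_only") +
                 person_days(flags, pop, "both"))
  # lowering the PM guideline never decreases person-days
  lower <- flag_sfap(pm_total, pm_fire, o3_total, o3_fire, pm_guideline = 10)
  expect_gte(person_days(lower, pop), person_days(flags, pop))
})

test_that("population-weighted means equal a weighted loop oracle", {
  set.seed(15)
  g <- grid_spec(0, 0, 1, 1, 3, 3)
  dates <- as.Date("2018-01-01") + 0:6
  conc <- daily_field(g, dates, array(runif(63, 0, 30), c(7, 3, 3)))
  counts <- matrix(rpois(9, 50) + 1, 3, 3)
  pop <- population_raster(g, 2018, counts, matrix(1L, 3, 3),
                           c("1" = sum(counts)))
  num <- 0; den <- 0
  for (i in 1:3) for (j in 1:3) {
    num <- num + counts[i, j] * mean(conc$values[, i, j])
    den <- den + counts[i, j]
  }
  expect_equal(pop_weighted_mean(conc, pop), num / den, tolerance = 1e-10)
  # uniform weights reduce to the arithmetic mean of cell means
  popu <- population_raster(g, 2018, matrix(10, 3, 3), matrix(1L, 3, 3),
                            c("1" = 90))
  expect_equal(pop_weighted_mean(conc, popu),
               mean(apply(conc$values, c(2, 3), mean)), tolerance = 1e-12)
  # point mass selects that cell's mean
  m <- matrix(0, 3, 3); m[2, 2] <- 7
  ctry <- matrix(NA_integer_, 3, 3); ctry[2, 2] <- 1L
  popp <- population_raster(g, 2018, m, ctry, c("1" = 7))
  expect_equal(pop_weighted_mean(conc, popp), mean(conc$values[, 2, 2]))
})

test_that("population aggregation conserves totals and matches a loop oracle", {
  # coarse cell edges at 0.0 / 0.5 / 1.0 so the 0.25-deg fine cells nest
  coarse <- grid_spec(0.25, 0.25, 0.5, 0.5, 2, 2)
  set.seed(16)
  fine2 <- grid_spec(0.125, 0.125, 0.25, 0.25, 4, 4)
  counts2 <- matrix(rpois(16, 10), 4, 4)
  agg <- aggregate_population(counts2, fine2, coarse, year = 2018)
  expect_equal(sum(agg$counts), sum(counts2))
  for (ci in 1:2) for (cj in 1:2)
    expect_equal(agg$counts[ci, cj],
                 sum(counts2[(2 * ci - 1):(2 * ci), (2 * cj - 1):(2 * cj)]))
  # 4 fine cells of 10 in one target cell -> 40
  agg2 <- aggregate_population(matrix(10, 2, 2),
                               grid_spec(0.125, 0.125, 0.25, 0.25, 2, 2),
                               grid_spec(0.25, 0.25, 0.5, 0.5, 1, 1),
                               year = 2018)
  expect_equal(agg2$counts[1, 1], 40)
})

test_that("reference adjustment scales each country to its total", {
  g <- grid_spec(0, 0, 1, 1, 2, 2)
  counts <- matrix(c(300, 500, 200, 100), 2, 2)
  ctry <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  pop <- population_raster(g, 2018, counts, ctry,
                           c("1" = 1000, "2" = 450))
  adj <- adjust_to_reference(pop)
  # country 1 raster sum 800, reference 1000 -> coefficient 1.25
  expect_equal(unname(attr(adj, "coefficients")["1"]), 1.25)
  expect_equal(adj$counts[, 1], counts[, 1] * 1.25)
  sums <- tapply(as.vector(adj$counts), as.vector(ctry), sum)
  expect_equal(as.numeric(sums), c(1000, 450), tolerance = 1e-6)
  # identity when reference equals the raster sum
  pop2 <- population_raster(g, 2018, counts, ctry, c("1" = 800, "2" = 300))
  expect_equal(adjust_to_reference(pop2)$counts, counts)
  # idempotence
  expect_equal(adjust_to_reference(adj)$counts, adj$counts, tolerance = 1e-12)
  # zero raster sum with positive reference is unresolvable
  counts3 <- counts; counts3[, 2] <- 0
  ctry3 <- ctry; ctry3[counts3 == 0] <- 2L
  pop3 <- population_raster(g, 2018, counts3, ctry3, c("1" = 1000, "2" = 450))
  expect_error(adjust_to_reference(pop3), "zero raster sum")
})
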