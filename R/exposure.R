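# Population exposure mapping: UN-consistent population adjustment, SFAP-day
# flagging, and the four exposure metrics (person-days, days per person,
# people exposed, population-weighted means) with the PM-only / O3-only /
# both category decomposition.

#' Annual gridded population raster
#'
#' Per-cell person counts on a [grid_spec()], a per-cell country label, and
#' country reference totals (e.g. UN population estimates) that the raster
#' can be adjusted to match.
#'
#' @param grid A [grid_spec()].
#' @param year Calendar year of the counts.
#' @param counts Numeric matrix `(nlat, nlon)` of person counts, >= 0.
#' @param country_id Integer matrix of country labels (`NA` or 0 = no
#'   country); every populated cell must carry a label.
#' @param ref_totals Named numeric vector of reference totals, names =
#'   country ids present in `country_id`.
#' @return An object of class `population_raster`.
#' @export
population_raster <- function(grid, year, counts, country_id, ref_totals) {
  counts <- as.matrix(counts); country_id <- as.matrix(country_id)
  stopifnot(all(dim(counts) == c(grid$nlat, grid$nlon)),
            all(dim(country_id) == c(grid$nlat, grid$nlon)))
  if (any(counts < 0, na.rm = TRUE))
    stop("population_raster: counts must be >= 0")
  pop_cells <- !is.na(counts) & counts > 0
  lab <- country_id[pop_cells]
  if (any(is.na(lab) | lab == 0))
    stop("population_raster: every populated cell needs a country_id")
  present <- unique(lab)
  if (!all(as.character(present) %in% names(ref_totals)))
    stop("population_raster: reference totals missing for some countries")
  if (any(ref_totals[as.character(present)] <= 0))
    stop("population_raster: reference totals must be > 0")
  structure(list(grid = grid, year = as.integer(year), counts = counts,
                 country_id = country_id, ref_totals = ref_totals),
            class = "population_raster")
}

#' Read a population raster from its CSV pair
#'
#' Inverse of the population files emitted by [write_world()]: a cell table
#' (`ilat, ilon, count, country_id`) plus a reference-totals table
#' (`country_id, reference_total`).
#'
#' @param cells_path,ref_path CSV paths.
#' @param grid The [grid_spec()] the indices refer to.
#' @param year Calendar year.
#' @return A [population_raster()].
#' @export
read_population_csv <- function(cells_path, ref_path, grid, year) {
  df <- utils::read.csv(cells_path)
  ref <- utils::read.csv(ref_path)
  counts <- matrix(0, grid$nlat, grid$nlon)
  ctry <- matrix(NA_integer_, grid$nlat, grid$nlon)
  counts[cbind(df$ilat, df$ilon)] <- df$count
  ctry[cbind(df$ilat, df$ilon)] <- df$country_id
  population_raster(grid, year, counts, ctry,
                    stats::setNames(ref$reference_total,
                                    as.character(ref$country_id)))
}

#' Aggregate a fine population raster onto a coarser nesting grid
#'
#' Per-cell sums of the contained fine counts; the global total is conserved
#' exactly. The country label of a coarse cell is the label holding the
#' largest aggregated population within it.
#'
#' @param fine_counts Numeric matrix of counts on `fine_grid`.
#' @param fine_grid,target [grid_spec()]s; `fine_grid` must nest in `target`.
#' @param country_id Optional fine country-label matrix.
#' @param ref_totals Optional reference totals carried through.
#' @param year Calendar year.
#' @return A [population_raster()] on `target`.
#' @export
aggregate_population <- function(fine_counts, fine_grid, target,
                                 country_id = NULL, ref_totals = NULL,
                                 year = NA_integer_) {
  idx <- nest_indices(fine_grid, target)
  counts <- matrix(0, target$nlat, target$nlon)
  ctry <- matrix(NA_integer_, target$nlat, target$nlon)
  for (ci in seq_len(target$nlat)) for (cj in seq_len(target$nlon)) {
    rows <- which(idx$ilat == ci); cols <- which(idx$ilon == cj)
    block <- fine_counts[rows, cols, drop = FALSE]
    counts[ci, cj] <- sum(block)
    if (!is.null(country_id) && counts[ci, cj] > 0) {
      labs <- country_id[rows, cols, drop = FALSE]
      tot <- tapply(as.vector(block), as.vector(labs), sum)
      ctry[ci, cj] <- as.integer(names(tot)[which.max(tot)])
    }
  }
  if (is.null(country_id)) {
    ctry[counts > 0] <- 1L
    if (is.null(ref_totals)) ref_totals <- c("1" = sum(counts))
  }
  population_raster(target, year, counts, ctry, ref_totals)
}

#' Adjust a population raster to country reference totals
#'
#' Every cell count is multiplied by its country's adjustment coefficient
#' (reference total / country raster sum), so post-adjustment country sums
#' equal the reference totals. Idempotent.
#'
#' @param raster A [population_raster()].
#' @return The adjusted [population_raster()], with the applied coefficients
#'   attached as attribute `"coefficients"`.
#' @export
adjust_to_reference <- function(raster) {
  labs <- as.vector(raster$country_id)
  cnts <- as.vector(raster$counts)
  keep <- !is.na(labs) & labs != 0
  sums <- tapply(cnts[keep], labs[keep], sum)
  for (cid in names(raster$ref_totals)) {
    s <- sums[cid]
    if ((is.na(s) || s == 0) && raster$ref_totals[cid] > 0 &&
        cid %in% as.character(unique(labs[keep])))
      stop("adjust_to_reference: country ", cid,
           " has zero raster sum but positive reference total")
  }
  coef <- raster$ref_totals[as.character(names(sums))] / as.numeric(sums)
  out <- raster$counts
  for (cid in names(sums)) {
    m <- !is.na(raster$country_id) & raster$country_id == as.integer(cid)
    out[m] <- raster$counts[m] * coef[cid]
  }
  res <- population_raster(raster$grid, raster$year, out, raster$country_id,
                           raster$ref_totals)
  attr(res, "coefficients") <- coef
  res
}

#' Flag substantial fire-sourced air pollution (SFAP) days
#'
#' A cell-day is an SFAP day when all-source PM2.5 exceeds `pm_guideline`
#' with a fire share of at least `min_frac`, and/or all-source daily-max-8h
#' O3 exceeds `o3_guideline` with a fire share of at least `min_frac`.
#' "Exceeds" is strict; negative fire values never satisfy the share rule.
#' Cell-days with any needed value missing are category `none` and counted
#' in `n_missing`.
#'
#' @param pm_total,pm_fire,o3_total,o3_fire Aligned [daily_field()]s.
#' @param pm_guideline PM2.5 daily guideline, ug/m3 (default 15).
#' @param o3_guideline O3 daily-max-8h guideline, ug/m3 (default 100).
#' @param min_frac Minimum fire share (default 0.5).
#' @return An object of class `sfap_flags`: integer category array
#'   `(date, lat, lon)` coded 0 = none, 1 = pm_only, 2 = o3_only, 3 = both,
#'   plus grid, dates and the missingness count.
#' @export
flag_sfap <- function(pm_total, pm_fire, o3_total, o3_fire,
                      pm_guideline = 15, o3_guideline = 100,
                      min_frac = 0.5) {
  check_aligned(pm_total, pm_fire); check_aligned(pm_total, o3_total)
  check_aligned(pm_total, o3_fire)
  pt <- pm_total$values; pf <- pm_fire$values
  ot <- o3_total$values; of <- o3_fire$values
  miss <- is.na(pt) | is.na(pf) | is.na(ot) | is.na(of)
  pm_hit <- !is.na(pt) & !is.na(pf) & pt > pm_guideline &
    pf >= 0 & pf >= min_frac * pt
  o3_hit <- !is.na(ot) & !is.na(of) & ot > o3_guideline &
    of >= 0 & of >= min_frac * ot
  category <- array(0L, dim(pt))
  category[pm_hit & !o3_hit] <- 1L
  category[o3_hit & !pm_hit] <- 2L
  category[pm_hit & o3_hit] <- 3L
  structure(list(grid = pm_total$grid, dates = pm_total$dates,
                 category = category, n_missing = sum(miss)),
            class = "sfap_flags")
}

sfap_flag_matrix <- function(flags) flags$category > 0L

#' Total person-days of SFAP exposure
#'
#' One person-day is one person exposed to one SFAP day: the sum over
#' cell-dates of the SFAP indicator times the cell population.
#'
#' @param flags An [flag_sfap()] result.
#' @param pop A [population_raster()] on the same grid.
#' @param category Optional: restrict to `"pm_only"`, `"o3_only"` or
#'   `"both"`; default all SFAP days.
#' @return Person-days (scalar).
#' @export
person_days <- function(flags, pop, category = NULL) {
  if (!grids_equal(flags$grid, pop$grid))
    stop("person_days: flags and population on different grids")
  sel <- if (is.null(category)) flags$category > 0L else
    flags$category == match(category, c("pm_only", "o3_only", "both"))
  days_per_cell <- apply(sel, c(2, 3), sum)
  sum(days_per_cell * pop$counts)
}

#' Average SFAP days per person
#'
#' @param pd Person-days, as from [person_days()].
#' @param pop A [population_raster()]; total population must be positive.
#' @return Days per person (scalar).
#' @export
days_per_person <- function(pd, pop) {
  total <- sum(pop$counts)
  if (total <= 0) stop("days_per_person: total population is zero")
  pd / total
}

#' People exposed to at least one SFAP day
#'
#' Counts the whole population of every cell with one or more flagged days
#' in the period covered by `flags` (normally one calendar year).
#'
#' @inheritParams person_days
#' @return Persons (scalar).
#' @export
people_exposed <- function(flags, pop) {
  if (!grids_equal(flags$grid, pop$grid))
    stop("people_exposed: flags and population on different grids")
  any_day <- apply(flags$category > 0L, c(2, 3), any)
  sum(pop$counts[any_day])
}

#' Population-weighted mean concentration
#'
#' Cell means over the period, averaged with cell population weights:
#' `sum(pop_c * mean_c) / sum(pop_c)` over cells with any data.
#'
#' @param conc A [daily_field()].
#' @param pop A [population_raster()] on the same grid.
#' @param period Optional `Date` vector restricting the averaging period.
#' @return Weighted mean in the field's units; `NA` if no data in period.
#' @export
pop_weighted_mean <- function(conc, pop, period = NULL) {
  if (!grids_equal(conc$grid, pop$grid))
    stop("pop_weighted_mean: field and population on different grids")
  sel <- if (is.null(period)) seq_along(conc$dates) else
    which(conc$dates %in% as.Date(period))
  if (!length(sel)) stop("pop_weighted_mean: empty period overlap")
  cm <- apply(conc$values[sel, , , drop = FALSE], c(2, 3),
              function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  ok <- !is.na(cm)
  if (!any(ok)) return(NA_real_)
  sum(pop$counts[ok] * cm[ok]) / sum(pop$counts[ok])
}

#' Annual exposure summary for one region-year
#'
#' Bundles the four exposure metrics plus the category decomposition. The
#' partition identity `person_days == pm_only + o3_only + both` holds by
#' construction.
#'
#' @param flags An [flag_sfap()] result covering one calendar year.
#' @param pop The matching-year [population_raster()].
#' @param pm_fire,o3_fire Fire-sourced concentration fields for the
#'   population-weighted means (optional).
#' @param region Region label for the output row.
#' @return One-row `data.frame` with columns `region, year, person_days,
#'   person_days_pm_only, person_days_o3_only, person_days_both,
#'   days_per_person, people_exposed, total_population, pw_mean_pm25_fire,
#'   pw_mean_o3_fire`.
#' @export
exposure_summary <- function(flags, pop, pm_fire = NULL, o3_fire = NULL,
                             region = "all") {
  pd <- person_days(flags, pop)
  data.frame(
    region = region, year = pop$year,
    person_days = pd,
    person_days_pm_only = person_days(flags, pop, "pm_only"),
    person_days_o3_only = person_days(flags, pop, "o3_only"),
    person_days_both = person_days(flags, pop, "both"),
    days_per_person = days_per_person(pd, pop),
    people_exposed = people_exposed(flags, pop),
    total_population = sum(pop$counts),
    pw_mean_pm25_fire = if (is.null(pm_fire)) NA_real_ else
      pop_weighted_mean(pm_fire, pop),
    pw_mean_o3_fire = if (is.null(o3_fire)) NA_real_ else
      pop_weighted_mean(o3_fire, pop),
    stringsAsFactors = FALSE)
}
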