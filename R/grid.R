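#' Regular latitude-longitude grid specification
#'
#' Defines a center-registered regular grid. Latitudes are stored ascending;
#' longitudes are normalized into [-180, 180). All gridded objects in the
#' package (daily fields, population rasters) share this specification, so a
#' single coordinate convention governs every spatial join.
#'
#' @param lat0,lon0 Center coordinates of the first (south-west) cell, degrees.
#' @param dlat,dlon Cell size in degrees; must be positive.
#' @param nlat,nlon Number of cells along each axis.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(lat0 = -9.875, lon0 = 110.125, dlat = 0.25, dlon = 0.25,
#'                nlat = 40, nlon = 60)
#' grid_lats(g)[1:3]
#' @export
grid_spec <- function(lat0, lon0, dlat, dlon, nlat, nlon) {
  stopifnot(is.numeric(lat0), is.numeric(lon0), dlat > 0, dlon > 0,
            nlat >= 1, nlon >= 1)
  lon0 <- normalize_lon(lon0)
  latN <- lat0 + (nlat - 1) * dlat
  if (lat0 <= -90 || latN >= 90)
    stop("grid_spec: cell centers must lie strictly within (-90, 90) latitude")
  structure(
    list(lat0 = lat0, lon0 = lon0, dlat = dlat, dlon = dlon,
         nlat = as.integer(nlat), nlon = as.integer(nlon)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells, %.4g x %.4g deg, origin (%.4f, %.4f)\n",
              x$nlat, x$nlon, x$dlat, x$dlon, x$lat0, x$lon0))
  invisible(x)
}

normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of cell-center latitudes (ascending) or longitudes.
#' @export
grid_lats <- function(grid) grid$lat0 + (seq_len(grid$nlat) - 1) * grid$dlat

#' @rdname grid_lats
#' @export
grid_lons <- function(grid) grid$lon0 + (seq_len(grid$nlon) - 1) * grid$dlon

grids_equal <- function(a, b, tol = 1e-9) {
  a$nlat == b$nlat && a$nlon == b$nlon &&
    abs(a$lat0 - b$lat0) < tol && abs(a$lon0 - b$lon0) < tol &&
    abs(a$dlat - b$dlat) < tol && abs(a$dlon - b$dlon) < tol
}

#' Locate the grid cell containing a point
#'
#' Returns the index of the cell whose center is nearest the point; a point
#' lying exactly on the shared edge of two cells is assigned to the lower
#' index. This is the deterministic station-to-grid linkage used throughout
#' the pipeline.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Point coordinates in degrees.
#' @return Integer vector `c(ilat, ilon)` (1-based).
#' @export
locate_cell <- function(grid, lon, lat) {
  lon <- normalize_lon(lon)
  ti <- (lat - grid$lat0) / grid$dlat
  tj <- (lon - grid$lon0) / grid$dlon
  # bounding box = outer cell edges
  if (ti < -0.5 || ti > grid$nlat - 0.5 || tj < -0.5 || tj > grid$nlon - 0.5)
    stop(sprintf("locate_cell: point (%g, %g) outside grid domain", lon, lat))
  # nearest center; exact midpoints resolve to the lower index
  i <- as.integer(ceiling(ti - 0.5)) + 1L
  j <- as.integer(ceiling(tj - 0.5)) + 1L
  i <- min(max(i, 1L), grid$nlat)
  j <- min(max(j, 1L), grid$nlon)
  c(i, j)
}

#' Map every fine cell of one grid onto its enclosing coarse cell
#'
#' Requires the coarse cell size to be an integer multiple of the fine size.
#' Used for block means (conservation checks) and population aggregation.
#'
#' @param fine,coarse [grid_spec()] objects; `fine` must nest within `coarse`.
#' @return List with integer matrices `ilat`, `ilon` (nlat_f x nlon_f is
#'   collapsed to vectors over each axis): `ilat[i]` is the coarse row of fine
#'   row `i`, `ilon[j]` the coarse column of fine column `j`.
#' @keywords internal
nest_indices <- function(fine, coarse) {
  rlat <- coarse$dlat / fine$dlat
  rlon <- coarse$dlon / fine$dlon
  if (abs(rlat - round(rlat)) > 1e-8 || abs(rlon - round(rlon)) > 1e-8)
    stop("grids do not nest: coarse cell size is not an integer multiple of fine")
  ilat <- vapply(grid_lats(fine), function(la) locate_cell(coarse, coarse$lon0, la)[1], 1L)
  ilon <- vapply(grid_lons(fine), function(lo) locate_cell(coarse, lo, coarse$lat0)[2], 1L)
  list(ilat = ilat, ilon = ilon)
}
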