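# Inverse-distance-weighted downscaling of coarse chemical-transport fields
# onto the fine analysis grid. Distances are great-circle kilometres so the
# zonal shrinking of longitude at high latitude is weighted correctly.

#' Great-circle (haversine) distance
#'
#' Spherical distance on an Earth of radius 6371.0 km. Symmetric, zero iff
#' the points coincide. At the equator one 0.25 degree cell spans about
#' 27.8 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees; vectorized.
#' @return Distance in kilometres.
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Inverse-distance-weighting parameters
#'
#' @param power Distance-decay exponent (> 0); default 2.
#' @param k Number of nearest coarse neighbours used per fine cell; default 4.
#' @param coincident_tol Tolerance in degrees within which a fine center is
#'   considered coincident with a coarse center and copies its value exactly.
#' @return An object of class `idw_params`.
#' @export
idw_params <- function(power = 2, k = 4, coincident_tol = 1e-6) {
  stopifnot(power > 0, k >= 1)
  structure(list(power = power, k = as.integer(k),
                 coincident_tol = coincident_tol), class = "idw_params")
}

#' Downscale a coarse daily field onto a fine grid by IDW interpolation
#'
#' Each fine cell-center value is the inverse-distance-weighted average of
#' the `k` nearest non-missing coarse cell centers, with weights
#' `d^(-power)` on great-circle distance. A fine center coincident with a
#' coarse center copies that center's value exactly. Output values are
#' bounded by the extremes of the contributing neighbours; if every
#' neighbour is missing on a date, the fine cell-date is `NA`.
#'
#' @param coarse A coarse-grid [daily_field()].
#' @param target The fine [grid_spec()]; must overlap the coarse domain.
#' @param params An [idw_params()].
#' @return A [daily_field()] on `target` with the same dates.
#' @export
idw_downscale <- function(coarse, target, params = idw_params()) {
  g <- coarse$grid
  clats <- rep(grid_lats(g), times = g$nlon)
  clons <- rep(grid_lons(g), each = g$nlat)
  flats <- rep(grid_lats(target), times = target$nlon)
  flons <- rep(grid_lons(target), each = target$nlat)
  nf <- length(flats); nc <- length(clats)
  span <- function(x, d) range(x) + c(-d, d) / 2
  lat_ok <- flats >= span(clats, g$dlat)[1] - g$dlat &
            flats <= span(clats, g$dlat)[2] + g$dlat
  if (!any(lat_ok)) stop("idw_downscale: empty overlap between target and coarse domain")

  # distance matrix fine x coarse; neighbour order per fine cell
  dmat <- matrix(0, nf, nc)
  for (ci in seq_len(nc))
    dmat[, ci] <- great_circle_km(flons, flats, clons[ci], clats[ci])
  ord <- matrix(apply(dmat, 1, order), nrow = nf, byrow = TRUE)
  k <- min(params$k, nc)

  coincide <- integer(nf)  # coarse index the fine center coincides with, 0 if none
  for (fi in seq_len(nf)) {
    ci <- ord[fi, 1]
    if (abs(flats[fi] - clats[ci]) <= params$coincident_tol &&
        abs(normalize_lon(flons[fi] - clons[ci])) <= params$coincident_tol)
      coincide[fi] <- ci
  }

  # precomputed normalized weight matrix for the complete-data fast path
  W <- matrix(0, nf, nc)
  for (fi in seq_len(nf)) {
    if (coincide[fi] > 0) { W[fi, coincide[fi]] <- 1; next }
    nb <- ord[fi, seq_len(k)]
    d <- dmat[fi, nb]
    if (d[1] <= 1e-9) { W[fi, nb[1]] <- 1; next }
    w <- d^(-params$power)
    W[fi, nb] <- w / sum(w)
  }

  nd <- length(coarse$dates)
  out <- array(NA_real_, c(nd, target$nlat, target$nlon))
  # fine cells are column-major in (lat, lon) by construction of flats/flons
  for (t in seq_len(nd)) {
    vc <- as.vector(coarse$values[t, , ])  # column-major: lat fastest
    if (all(is.na(vc))) stop("idw_downscale: all coarse values missing on date ",
                             format(coarse$dates[t]))
    miss <- is.na(vc)
    if (!any(miss)) {
      est <- as.vector(W %*% vc)
    } else {
      est <- rep(NA_real_, nf)
      for (fi in seq_len(nf)) {
        if (coincide[fi] > 0 && !miss[coincide[fi]]) {
          est[fi] <- vc[coincide[fi]]
          next
        }
        nb <- ord[fi, ]
        nb <- nb[!miss[nb]]
        if (!length(nb)) next
        nb <- nb[seq_len(min(k, length(nb)))]
        d <- dmat[fi, nb]
        if (d[1] <= 1e-9) { est[fi] <- vc[nb[1]]; next }
        w <- d^(-params$power)
        est[fi] <- sum(w * vc[nb]) / sum(w)
      }
    }
    out[t, , ] <- matrix(est, target$nlat, target$nlon)
  }
  daily_field(target, coarse$dates, out, coarse$variable, coarse$units,
              nonneg = FALSE)
}
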