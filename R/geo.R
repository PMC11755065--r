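# Geodesy helpers shared across modules. All great-circle computations use a
# spherical Earth of radius 6371 km so that 1 degree of latitude = 111.19 km.

EARTH_RADIUS_M <- 6371000

#' Great-circle distance in kilometres
#'
#' Haversine distance between points given as lon/lat degrees.
#'
#' @param p1,p2 Two-column matrices or length-2 vectors of (lon, lat) degrees.
#' @return Distance(s) in km.
#' @keywords internal
gc_dist_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M) / 1000
}

#' Initial bearing from p1 to p2 in [0, 360)
#' @keywords internal
gc_bearing <- function(p1, p2) {
  b <- geosphere::bearing(p1, p2)
  (b + 360) %% 360
}

#' Project lon/lat to a local azimuthal equidistant plane (metres)
#'
#' Coordinates are (x east, y north) about `origin`; distances from the origin
#' are preserved exactly, which is what a metric kernel grid needs.
#'
#' @param lonlat two-column matrix of (lon, lat) degrees.
#' @param origin length-2 (lon, lat) of the projection centre (the colony).
#' @return matrix with columns x, y in metres.
#' @keywords internal
project_aeqd <- function(lonlat, origin) {
  lonlat <- matrix(as.numeric(unlist(lonlat)), ncol = 2)
  d <- geosphere::distHaversine(origin, lonlat, r = EARTH_RADIUS_M)
  b <- geosphere::bearing(matrix(origin, nrow(lonlat), 2, byrow = TRUE),
                          lonlat) * pi / 180
  b[is.na(b)] <- 0  # coincident with origin
  cbind(x = d * sin(b), y = d * cos(b))
}

#' Inverse of [project_aeqd()]
#' @keywords internal
unproject_aeqd <- function(xy, origin) {
  xy <- matrix(as.numeric(unlist(xy)), ncol = 2)
  d <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  b <- atan2(xy[, 1], xy[, 2]) * 180 / pi
  out <- geosphere::destPoint(origin, b, d, r = EARTH_RADIUS_M)
  out[d == 0, 1] <- origin[1]
  out[d == 0, 2] <- origin[2]
  colnames(out) <- c("lon", "lat")
  out
}

#' Position a fraction of the way along a great circle
#'
#' Exact spherical linear interpolation between the two endpoints' unit
#' vectors; `f = 0.5` is the great-circle midpoint.
#'
#' @keywords internal
gc_interpolate <- function(p1, p2, f) {
  to_xyz <- function(p) {
    la <- p[2] * pi / 180; lo <- p[1] * pi / 180
    c(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  a <- to_xyz(as.numeric(p1)); b <- to_xyz(as.numeric(p2))
  omega <- acos(min(1, max(-1, sum(a * b))))
  f <- pmin(pmax(f, 0), 1)
  if (omega < 1e-12) {
    v <- matrix(a, length(f), 3, byrow = TRUE)
  } else {
    w1 <- sin((1 - f) * omega) / sin(omega)
    w2 <- sin(f * omega) / sin(omega)
    v <- cbind(w1 * a[1] + w2 * b[1], w1 * a[2] + w2 * b[2],
               w1 * a[3] + w2 * b[3])
    v <- v / sqrt(rowSums(v^2))
  }
  cbind(lon = atan2(v[, 2], v[, 1]) * 180 / pi,
        lat = asin(pmin(1, pmax(-1, v[, 3]))) * 180 / pi)
}
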