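#' Project lon/lat to local azimuthal-equidistant coordinates
#'
#' Projects WGS84 coordinates into a planar x/y frame (km) centred on a
#' reference point, preserving great-circle distance and initial bearing from
#' that point. Used for track interpolation and the 1 km dive-time grid so
#' that all trips of all individuals share one planar frame anchored at the
#' colony.
#'
#' @param lon,lat numeric vectors, degrees (WGS84).
#' @param origin length-2 numeric `c(lon, lat)` of the projection centre.
#' @return matrix with columns `x`, `y` in kilometres (x east, y north).
#' @export
project_aeq <- function(lon, lat, origin) {
  stopifnot(length(origin) == 2, length(lon) == length(lat))
  if (length(lon) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  pts <- cbind(lon, lat)
  d <- geosphere::distGeo(origin, pts) / 1000
  b <- geosphere::bearing(rbind(origin), pts)
  b[is.na(b)] <- 0 # point coincides with origin
  rad <- b * pi / 180
  cbind(x = d * sin(rad), y = d * cos(rad))
}

#' Inverse of [project_aeq()]
#'
#' @param x,y numeric vectors, kilometres in the local frame.
#' @param origin length-2 numeric `c(lon, lat)`.
#' @return matrix with columns `lon`, `lat` in degrees.
#' @export
unproject_aeq <- function(x, y, origin) {
  stopifnot(length(origin) == 2, length(x) == length(y))
  if (length(x) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("lon", "lat"))))
  }
  d <- sqrt(x^2 + y^2) * 1000
  b <- atan2(x, y) * 180 / pi
  p <- geosphere::destPoint(rbind(origin), b, d)
  colnames(p) <- c("lon", "lat")
  p
}

#' Great-circle distance from a reference point, in km
#' @param lon,lat numeric vectors, degrees.
#' @param ref length-2 `c(lon, lat)`.
#' @return numeric vector of distances (km).
#' @export
gc_dist_km <- function(lon, lat, ref) {
  if (length(lon) == 0L) return(numeric(0))
  geosphere::distGeo(rbind(ref), cbind(lon, lat)) / 1000
}

#' Initial great-circle bearing from a reference point
#' @param lon,lat numeric scalars or vectors, degrees.
#' @param ref length-2 `c(lon, lat)`.
#' @return bearing(s) in degrees clockwise from true north, in \[0, 360).
#' @export
gc_bearing <- function(lon, lat, ref) {
  b <- geosphere::bearing(rbind(ref), cbind(lon, lat))
  b[is.na(b)] <- 0
  b %% 360
}

# Path length (km) of an ordered set of fixes, great-circle segment sum.
path_length_km <- function(lon, lat) {
  n <- length(lon)
  if (n < 2L) return(0)
  sum(geosphere::distGeo(cbind(lon[-n], lat[-n]), cbind(lon[-1], lat[-1]))) / 1000
}
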