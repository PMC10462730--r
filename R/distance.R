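#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised with the
#' usual recycling rules.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees
#'   (south/west negative).
#' @return Distance in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0) # one degree of meridian, ~111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * earth_radius_km() * asin(pmin(1, sqrt(a)))
}

earth_radius_km <- function() 6371.0

check_coords <- function(lat, lon) {
  if (any(!is.na(lat) & (lat < -90 | lat > 90)) ||
      any(!is.na(lon) & (lon < -180 | lon > 180))) {
    stop("coordinates out of range (lat in [-90, 90], lon in [-180, 180])",
         call. = FALSE)
  }
  invisible(NULL)
}

# n1 x n2 distance matrix between two coordinate sets
cross_distance_km <- function(lat1, lon1, lat2, lon2) {
  n1 <- length(lat1); n2 <- length(lat2)
  matrix(haversine_km(rep(lat1, times = n2), rep(lon1, times = n2),
                      rep(lat2, each = n1), rep(lon2, each = n1)),
         nrow = n1, ncol = n2)
}

#' Minimum distance from a reef to a storm track
#'
#' Minimum haversine distance from a point to the 6-hourly track vertices of
#' one storm (no segment interpolation); ties go to the earliest point.
#'
#' @param tracks Track points of a single storm (tibble with `lat`, `lon`).
#' @param lat,lon Reef coordinates in decimal degrees.
#' @return A list with `distance_km` and `closest_point` (row index into
#'   `tracks`).
#' @export
min_track_distance <- function(tracks, lat, lon) {
  stopifnot(nrow(tracks) >= 1)
  d <- haversine_km(lat, lon, tracks$lat, tracks$lon)
  i <- which.min(d)
  list(distance_km = d[i], closest_point = i)
}
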