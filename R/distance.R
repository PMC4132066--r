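#' Great-circle distance between points (haversine)
#'
#' Distance kernel used by every spatial rule in the package: speed
#' filtering, trip summaries, dyadic distances and nest-distance matrices.
#' Computed on a sphere of radius 6,371,000 m; vectorised over all
#' arguments with the usual recycling.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @param radius Sphere radius in metres.
#' @return Distance(s) in metres; symmetric and non-negative.
#' @examples
#' haversine_m(0, 0, 0, 1)  # one degree of longitude at the equator
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2, radius = 6371000) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * radius * asin(sqrt(a))
}
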