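# WGS84 <-> UTM zone 32N (EPSG:4326 <-> EPSG:32632) coordinate transform.
# Standard series expansion for the transverse Mercator projection on the
# WGS84 ellipsoid (Snyder-style terms); centimeter-level accuracy within the
# zone, ample for kilometer-lattice work.

.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)
.utm32 <- list(lon0 = 9 * pi / 180, k0 = 0.9996, fe = 500000, fn = 0)

utm32_forward <- function(lon_deg, lat_deg) {
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  lat <- lat_deg * pi / 180; lon <- lon_deg * pi / 180
  k0 <- .utm32$k0
  sinl <- sin(lat); cosl <- cos(lat)
  N <- a / sqrt(1 - e2 * sinl^2)
  T <- tan(lat)^2
  C <- ep2 * cosl^2
  A <- cosl * (lon - .utm32$lon0)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * lat -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * lat) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * lat) -
            (35 * e2^3 / 3072) * sin(6 * lat))
  x <- .utm32$fe + k0 * N *
    (A + (1 - T + C) * A^3 / 6 +
       (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120)
  y <- .utm32$fn + k0 *
    (M + N * tan(lat) * (A^2 / 2 +
       (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
       (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  cbind(x = x, y = y)
}

utm32_inverse <- function(x, y) {
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  k0 <- .utm32$k0
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  M <- (y - .utm32$fn) / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu +
    (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  sinp <- sin(phi1); cosp <- cos(phi1)
  C1 <- ep2 * cosp^2
  T1 <- tan(phi1)^2
  N1 <- a / sqrt(1 - e2 * sinp^2)
  R1 <- a * (1 - e2) / (1 - e2 * sinp^2)^1.5
  D <- (x - .utm32$fe) / (N1 * k0)
  lat <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 -
       (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) *
         D^6 / 720)
  lon <- .utm32$lon0 +
    (D - (1 + 2 * T1 + C1) * D^3 / 6 +
       (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
         D^5 / 120) / cosp
  cbind(x = lon * 180 / pi, y = lat * 180 / pi)
}

.supported_crs <- c("EPSG:32632", "EPSG:4326")

#' Transform point coordinates between supported CRSs
#'
#' Supports the two CRSs the processing levels use: `EPSG:32632` (UTM zone
#' 32N, meters) and `EPSG:4326` (WGS84 geographic, degrees).
#'
#' @param x,y Numeric coordinate vectors in `from` units (lon/lat order for
#'   `EPSG:4326`).
#' @param from,to CRS identifiers.
#' @return Two-column matrix of transformed `x`, `y`.
#' @examples
#' transform_points(11.5, 45.5, "EPSG:4326", "EPSG:32632")
#' @export
transform_points <- function(x, y, from, to) {
  if (!(from %in% .supported_crs) || !(to %in% .supported_crs))
    stop(sprintf("unsupported CRS (supported: %s)",
                 paste(.supported_crs, collapse = ", ")), call. = FALSE)
  if (from == to) return(cbind(x = as.numeric(x), y = as.numeric(y)))
  if (from == "EPSG:4326") utm32_forward(x, y) else utm32_inverse(x, y)
}
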