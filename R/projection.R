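# Transverse-Mercator (UTM) projection on the WGS84 ellipsoid, from the
# standard series expansions (Snyder 1987, Map Projections - A Working
# Manual, eqs 8-9..8-25). Millimetre-level accuracy within a zone, verified
# against geodesic distances in the test suite.

.wgs84_a <- 6378137
.wgs84_f <- 1 / 298.257223563

utm_params <- function(zone = 33) {
  list(zone = zone, lon0 = (zone - 0.5) * 6 - 180, k0 = 0.9996,
       fe = 500000, fn = 0)
}

#' Choose a UTM zone from a longitude
#' @param lon longitude in degrees
#' @return integer UTM zone
#' @export
utm_zone_from_lon <- function(lon) {
  as.integer(floor((lon + 180) / 6) + 1)
}

#' Project WGS84 lon/lat to UTM coordinates
#'
#' @param lon,lat coordinates in degrees (vectors)
#' @param zone UTM zone number (northern hemisphere assumed)
#' @return matrix with columns `x`, `y` in metres
#' @export
utm_project <- function(lon, lat, zone = 33) {
  pr <- utm_params(zone)
  a <- .wgs84_a; f <- .wgs84_f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  dl <- (lon - pr$lon0) * pi / 180
  sphi <- sin(phi); cphi <- cos(phi)
  N <- a / sqrt(1 - e2 * sphi^2)
  T <- tan(phi)^2
  C <- ep2 * cphi^2
  A <- dl * cphi
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- pr$fe + pr$k0 * N * (A + (1 - T + C) * A^3 / 6 +
        (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120)
  y <- pr$fn + pr$k0 * (M + N * tan(phi) * (A^2 / 2 +
        (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
        (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  cbind(x = x, y = y)
}

#' Inverse UTM projection to WGS84 lon/lat
#'
#' @param x,y UTM coordinates in metres (vectors)
#' @param zone UTM zone number (northern hemisphere assumed)
#' @return matrix with columns `lon`, `lat` in degrees
#' @export
utm_unproject <- function(x, y, zone = 33) {
  pr <- utm_params(zone)
  a <- .wgs84_a; f <- .wgs84_f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  M <- (y - pr$fn) / pr$k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  sphi <- sin(phi1); cphi <- cos(phi1)
  C1 <- ep2 * cphi^2
  T1 <- tan(phi1)^2
  N1 <- a / sqrt(1 - e2 * sphi^2)
  R1 <- a * (1 - e2) / (1 - e2 * sphi^2)^1.5
  D <- (x - pr$fe) / (N1 * pr$k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) * (D^2 / 2 -
        (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
        (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
          (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) / cphi
  cbind(lon = pr$lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}
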