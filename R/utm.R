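# WGS84 Transverse Mercator (UTM) forward and inverse transforms, standard
# series expansions (sub-metre accuracy within a zone). Written in-package:
# the analysis only needs one fixed zone and a round-trip guarantee.

.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

#' Project WGS84 coordinates to UTM
#'
#' Universal Transverse Mercator projection (metres) of geographic
#' coordinates. Defaults to zone 55 south, which covers the central Great
#' Barrier Reef; points far outside the zone's 6-degree width are projected
#' anyway (the analysis treats inter-array spans as planar) with a warning.
#'
#' @param longitude,latitude numeric degrees (WGS84), equal length.
#' @param zone UTM zone number (1-60), default 55.
#' @param south logical, southern hemisphere false-northing (default TRUE).
#' @return Tibble with `easting` and `northing` in metres.
#' @export
#' @examples
#' project_to_utm(147.06, -18.63)
project_to_utm <- function(longitude, latitude, zone = 55, south = TRUE) {
  if (any(!is.finite(longitude)) || any(!is.finite(latitude))) {
    abort("coordinates must be finite")
  }
  lon0 <- zone * 6 - 183
  if (any(abs(longitude - lon0) > 6)) {
    warn(sprintf("some longitudes are > 6 degrees from the zone %d meridian; projection distortion grows outside the zone", zone))
  }
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  phi <- latitude * pi / 180
  dlam <- (longitude - lon0) * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- dlam * cos(phi)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  easting <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                       (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) +
    500000
  northing <- k0 * (M + N * tan(phi) *
                    (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                     (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) northing <- northing + 10000000
  tibble::tibble(easting = easting, northing = northing)
}

#' Inverse UTM projection
#'
#' Inverse of [project_to_utm()]; `utm_to_lonlat(project_to_utm(...))`
#' agrees with the input to well under a metre anywhere in the zone.
#'
#' @param easting,northing metres.
#' @inheritParams project_to_utm
#' @return Tibble with `longitude` and `latitude` in degrees.
#' @export
utm_to_lonlat <- function(easting, northing, zone = 55, south = TRUE) {
  if (any(!is.finite(easting)) || any(!is.finite(northing))) {
    abort("coordinates must be finite")
  }
  a <- .wgs84$a; f <- .wgs84$f
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  lon0 <- zone * 6 - 183
  y <- northing - if (south) 10000000 else 0
  M <- y / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  C1 <- ep2 * cos(phi1)^2
  T1 <- tan(phi1)^2
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- (easting - 500000) / (N1 * k0)
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
     (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
          (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
            D^5 / 120) / cos(phi1)
  tibble::tibble(longitude = lon0 + lam * 180 / pi,
                 latitude = phi * 180 / pi)
}
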