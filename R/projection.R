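# Local transverse-Mercator projection (WGS84 ellipsoid, standard series).
# The study area spans < 10 km, so a TM frame centred on the data keeps
# planar distance error far below GPS accuracy.

.WGS84_A <- 6378137.0
.WGS84_F <- 1 / 298.257223563

#' Define a local transverse-Mercator frame
#'
#' Creates a projection descriptor centred on (`lon0`, `lat0`). Coordinates
#' projected with it are metres east/north of the centre (scale factor 1 on
#' the central meridian, false easting/northing chosen so the centre maps to
#' the origin).
#'
#' @param lon0,lat0 Centre of the frame, decimal degrees.
#' @return An object of class `tm_projection`.
#' @export
make_projection <- function(lon0, lat0) {
  stopifnot(is.finite(lon0), is.finite(lat0), abs(lat0) < 89)
  p <- structure(list(lon0 = lon0, lat0 = lat0), class = "tm_projection")
  org <- .tm_forward(lon0, lat0, lon0)
  p$x0 <- org$x
  p$y0 <- org$y
  p
}

.tm_consts <- function() {
  a <- .WGS84_A; f <- .WGS84_F
  e2 <- f * (2 - f)
  list(a = a, e2 = e2, ep2 = e2 / (1 - e2))
}

.meridian_arc <- function(phi, a, e2) {
  a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
         (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
         (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
         (35 * e2^3 / 3072) * sin(6 * phi))
}

.tm_forward <- function(lon, lat, lon0) {
  k <- .tm_consts()
  phi <- lat * pi / 180
  lam <- (lon - lon0) * pi / 180
  N <- k$a / sqrt(1 - k$e2 * sin(phi)^2)
  Tt <- tan(phi)^2
  C <- k$ep2 * cos(phi)^2
  A <- lam * cos(phi)
  M <- .meridian_arc(phi, k$a, k$e2)
  x <- N * (A + (1 - Tt + C) * A^3 / 6 +
              (5 - 18 * Tt + Tt^2 + 72 * C - 58 * k$ep2) * A^5 / 120)
  y <- M + N * tan(phi) *
    (A^2 / 2 + (5 - Tt + 9 * C + 4 * C^2) * A^4 / 24 +
       (61 - 58 * Tt + Tt^2 + 600 * C - 330 * k$ep2) * A^6 / 720)
  list(x = x, y = y)
}

.tm_inverse <- function(x, y, lon0) {
  k <- .tm_consts()
  e1 <- (1 - sqrt(1 - k$e2)) / (1 + sqrt(1 - k$e2))
  mu <- y / (k$a * (1 - k$e2 / 4 - 3 * k$e2^2 / 64 - 5 * k$e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  N1 <- k$a / sqrt(1 - k$e2 * sin(phi1)^2)
  R1 <- k$a * (1 - k$e2) / (1 - k$e2 * sin(phi1)^2)^1.5
  T1 <- tan(phi1)^2
  C1 <- k$ep2 * cos(phi1)^2
  D <- x / N1
  phi <- phi1 - (N1 * tan(phi1) / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * k$ep2) * D^4 / 24 +
       (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * k$ep2 - 3 * C1^2) * D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
            (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * k$ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)
  list(lon = lon0 + lam * 180 / pi, lat = phi * 180 / pi)
}

#' Project geographic coordinates to the local planar frame
#'
#' @param lon,lat Decimal degrees (vectors).
#' @param proj A `tm_projection` from [make_projection()].
#' @return A list with numeric vectors `x` and `y` in metres.
#' @export
project_lonlat <- function(lon, lat, proj) {
  stopifnot(inherits(proj, "tm_projection"))
  fw <- .tm_forward(lon, lat, proj$lon0)
  list(x = fw$x - proj$x0, y = fw$y - proj$y0)
}

#' Inverse-project planar coordinates to longitude/latitude
#'
#' @param x,y Metres in the frame of `proj`.
#' @param proj A `tm_projection`.
#' @return A list with numeric vectors `lon` and `lat` in degrees.
#' @export
unproject_xy <- function(x, y, proj) {
  stopifnot(inherits(proj, "tm_projection"))
  .tm_inverse(x + proj$x0, y + proj$y0, proj$lon0)
}

#' @export
print.tm_projection <- function(x, ...) {
  cat(sprintf("Local transverse-Mercator frame centred at %.4f E, %.4f N (WGS84)\n",
              x$lon0, x$lat0))
  invisible(x)
}
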