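# Spherical Lambert azimuthal equal-area projection. Hexagons must be
# constructed in a plane where areas are exact; LAEA gives that on the
# authalic sphere, with moderate shape distortion across an Atlantic-scale
# domain when centred mid-basin.

#' Earth radius used throughout (authalic sphere, km)
#' @keywords internal
#' @noRd
EARTH_RADIUS_KM <- 6371.0088

#' Define a Lambert azimuthal equal-area projection
#'
#' @param lon0,lat0 Projection centre in decimal degrees. The default
#'   (15 degrees W, 0 degrees N) sits mid-Atlantic so distortion is moderate
#'   over a 75 N to 62 S study domain.
#' @return An object of class `laea_proj`.
#' @examples
#' p <- laea_projection()
#' xy <- proj_forward(p, lon = -15, lat = 0)
#' xy # origin
#' @export
laea_projection <- function(lon0 = -15, lat0 = 0) {
  stopifnot(is.finite(lon0), is.finite(lat0), abs(lat0) <= 90)
  structure(
    list(lon0 = lon0, lat0 = lat0, radius_km = EARTH_RADIUS_KM),
    class = "laea_proj"
  )
}

#' @export
print.laea_proj <- function(x, ...) {
  cat(sprintf(
    "Lambert azimuthal equal-area projection, centre (%g, %g), sphere R = %.4f km\n",
    x$lon0, x$lat0, x$radius_km
  ))
  invisible(x)
}

#' Project lon/lat to planar X/Y kilometres (and back)
#'
#' `proj_forward()` maps WGS84-style longitude/latitude (degrees) to planar
#' equal-area coordinates in kilometres; `proj_inverse()` maps back.
#' Longitudes are normalised to \[-180, 180). The antipode of the projection
#' centre is not representable and maps to an error.
#'
#' @param proj A `laea_proj` object.
#' @param lon,lat Numeric vectors, degrees.
#' @param x,y Numeric vectors, kilometres.
#' @return A tibble with columns `x`, `y` (forward) or `lon`, `lat` (inverse).
#' @export
proj_forward <- function(proj, lon, lat) {
  stopifnot(inherits(proj, "laea_proj"))
  lon <- normalize_lon(lon)
  lam <- (lon - proj$lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- proj$lat0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  if (any(denom < 1e-10, na.rm = TRUE)) {
    stop("point at or near the projection antipode cannot be projected")
  }
  k <- sqrt(2 / denom)
  r <- proj$radius_km
  tibble::tibble(
    x = r * k * cos(phi) * sin(lam),
    y = r * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam))
  )
}

#' @rdname proj_forward
#' @export
proj_inverse <- function(proj, x, y) {
  stopifnot(inherits(proj, "laea_proj"))
  r <- proj$radius_km
  rho <- sqrt(x^2 + y^2)
  phi0 <- proj$lat0 * pi / 180
  cc <- 2 * asin(pmin(1, rho / (2 * r)))
  # guard rho == 0 (projection centre)
  safe_rho <- ifelse(rho == 0, 1, rho)
  phi <- asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / safe_rho)
  lam <- atan2(
    x * sin(cc),
    safe_rho * cos(cc) * cos(phi0) - y * sin(phi0) * sin(cc)
  )
  lon <- normalize_lon(proj$lon0 + lam * 180 / pi)
  lat <- phi * 180 / pi
  lon[rho == 0] <- proj$lon0
  lat[rho == 0] <- proj$lat0
  tibble::tibble(lon = lon, lat = lat)
}

#' Normalise longitudes to \[-180, 180)
#' @param lon Numeric vector of longitudes, degrees.
#' @return Numeric vector in \[-180, 180).
#' @export
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}
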