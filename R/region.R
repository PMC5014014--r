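# Region polygons (e.g. the Canary Current upwelling boundary): one or more
# lon/lat rings, first ring the outer boundary, later rings holes.
# Containment is even-odd, so holes fall out of the crossing count
# automatically; boundary points count as inside.

#' Create a region polygon
#'
#' @param name Region name.
#' @param rings A single two-column matrix/data frame (lon, lat) or a list of
#'   them; the first ring is the outer boundary, any others are holes. Rings
#'   may be given open or closed (first vertex repeated); they are stored
#'   open.
#' @return A `region_polygon` object.
#' @examples
#' r <- region_polygon("box", cbind(c(-20, -10, -10, -20), c(10, 10, 30, 30)))
#' point_in_region(r, -15, 20)
#' @export
region_polygon <- function(name, rings) {
  if (!is.list(rings) || is.data.frame(rings)) rings <- list(rings)
  rings <- lapply(rings, function(rg) {
    rg <- as.matrix(rg)
    if (ncol(rg) != 2) stop("each ring needs two columns (lon, lat)")
    storage.mode(rg) <- "double"
    # drop an explicit closing vertex
    n <- nrow(rg)
    if (n >= 2 && all(rg[1, ] == rg[n, ])) rg <- rg[-n, , drop = FALSE]
    if (nrow(rg) < 3) stop("each ring needs at least 3 distinct vertices")
    colnames(rg) <- c("lon", "lat")
    rg
  })
  structure(list(name = name, rings = rings), class = "region_polygon")
}

#' @export
print.region_polygon <- function(x, ...) {
  cat(sprintf(
    "region_polygon '%s': %d ring(s), %d vertices\n",
    x$name, length(x$rings), sum(vapply(x$rings, nrow, integer(1)))
  ))
  invisible(x)
}

#' Point-in-region test (even-odd rule, boundary inclusive)
#'
#' Even-odd (ray casting) containment in the lon/lat plane across all rings,
#' so holes are excluded; points exactly on a ring edge count as inside.
#'
#' @param region A `region_polygon`.
#' @param lon,lat Numeric vectors, degrees.
#' @return Logical vector.
#' @export
point_in_region <- function(region, lon, lat) {
  stopifnot(inherits(region, "region_polygon"), length(lon) == length(lat))
  if (length(lon) == 0) return(logical(0))
  if (any(!is.finite(lon) | !is.finite(lat))) {
    stop("point_in_region requires finite coordinates")
  }
  lon <- normalize_lon(lon)
  crossings <- integer(length(lon))
  boundary <- logical(length(lon))
  for (ring in region$rings) {
    n <- nrow(ring)
    x1 <- ring[, 1]
    y1 <- ring[, 2]
    x2 <- ring[c(2:n, 1), 1]
    y2 <- ring[c(2:n, 1), 2]
    for (e in seq_len(n)) {
      # boundary test: collinear and within the segment's bounding box
      dx <- x2[e] - x1[e]
      dy <- y2[e] - y1[e]
      cross <- dx * (lat - y1[e]) - dy * (lon - x1[e])
      on_seg <- abs(cross) < 1e-12 &
        lon >= pmin(x1[e], x2[e]) - 1e-12 & lon <= pmax(x1[e], x2[e]) + 1e-12 &
        lat >= pmin(y1[e], y2[e]) - 1e-12 & lat <= pmax(y1[e], y2[e]) + 1e-12
      boundary <- boundary | on_seg
      # half-open rule avoids double-counting vertices on the test ray
      straddles <- (y1[e] > lat) != (y2[e] > lat)
      if (any(straddles)) {
        xi <- x1[e] + (lat - y1[e]) / dy * dx
        crossings <- crossings + as.integer(straddles & lon < xi)
      }
    }
  }
  (crossings %% 2L == 1L) | boundary
}

#' Read/write region polygons as GeoJSON (RFC 7946)
#'
#' `write_region_geojson()` writes a Polygon feature; `read_region_geojson()`
#' accepts a Polygon or single-feature FeatureCollection.
#'
#' @param region A `region_polygon`.
#' @param path File path.
#' @return `read_region_geojson()` returns a `region_polygon`.
#' @export
write_region_geojson <- function(region, path) {
  stopifnot(inherits(region, "region_polygon"))
  coords <- lapply(region$rings, function(rg) {
    rbind(rg, rg[1, , drop = FALSE]) # GeoJSON rings are closed
  })
  gj <- list(
    type = "Feature",
    properties = list(name = region$name),
    geometry = list(type = "Polygon", coordinates = coords)
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_region_geojson
#' @export
read_region_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(gj$type, "FeatureCollection")) {
    if (length(gj$features) != 1) stop("expected a single-feature GeoJSON")
    gj <- gj$features[[1]]
  }
  if (!identical(gj$type, "Feature") || !identical(gj$geometry$type, "Polygon")) {
    stop("expected a GeoJSON Polygon feature")
  }
  rings <- lapply(gj$geometry$coordinates, function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  })
  name <- gj$properties$name
  if (is.null(name)) name <- "region"
  region_polygon(name, rings)
}
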