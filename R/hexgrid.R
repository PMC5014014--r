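# Equal-area tessellated hexagon grid. Hexagons are regular and pointy-top,
# laid out on an axial (q, r) lattice in the projected plane, so every cell
# has exactly equal projected area and same-row centres sit sqrt(3) * side
# apart. "Diameter" is read as the corner-to-corner circumdiameter, so a
# 200 km grid has side (= circumradius) 100 km.

#' Build an equal-area tessellated hexagon grid over a lon/lat domain
#'
#' Constructs a gap-free tiling of regular pointy-top hexagons, in a Lambert
#' azimuthal equal-area projection, covering the projected image of a
#' longitude/latitude bounding box. The returned set is the smallest set of
#' lattice cells whose hexagons intersect the projected domain rectangle
#' (rectangle defined by the projected bounding box of the domain outline).
#' Cell ids are stable for a fixed domain and diameter.
#'
#' @param domain Named list or vector with `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max` in degrees. Must not span a pole and must not cross the
#'   antimeridian.
#' @param circumdiameter_km Corner-to-corner hexagon diameter in km
#'   (default 200, i.e. side 100 km).
#' @param proj A `laea_proj` projection (default centred at 15 W, 0 N).
#' @return A `hex_grid` object: list with `cells` (tibble: `cell`, `q`, `r`,
#'   `x`, `y`, `lon`, `lat`, `ocean`), `side_km`, `circumdiameter_km`,
#'   `proj`, `domain`, and the projected domain rectangle `bbox_km`.
#' @examples
#' g <- build_hex_grid(list(lon_min = -20, lon_max = -10,
#'                          lat_min = 0, lat_max = 10))
#' hex_cell_area_km2(g) # 25980.76 for a 200 km circumdiameter
#' @export
build_hex_grid <- function(domain, circumdiameter_km = 200,
                           proj = laea_projection()) {
  domain <- as.list(domain)
  req <- c("lon_min", "lon_max", "lat_min", "lat_max")
  if (!all(req %in% names(domain))) {
    stop("domain must have lon_min, lon_max, lat_min, lat_max")
  }
  if (domain$lon_min >= domain$lon_max || domain$lat_min >= domain$lat_max) {
    stop("degenerate domain: require lon_min < lon_max and lat_min < lat_max")
  }
  if (domain$lat_min <= -90 || domain$lat_max >= 90) {
    stop("domains touching or spanning a pole are not supported")
  }
  if (circumdiameter_km <= 0) stop("circumdiameter_km must be positive")
  side <- circumdiameter_km / 2

  # projected bounding rectangle of the domain outline (edges curve under
  # projection, so sample the outline densely rather than the 4 corners)
  ns <- 201
  lon_seq <- seq(domain$lon_min, domain$lon_max, length.out = ns)
  lat_seq <- seq(domain$lat_min, domain$lat_max, length.out = ns)
  outline <- rbind(
    cbind(lon_seq, domain$lat_min),
    cbind(lon_seq, domain$lat_max),
    cbind(domain$lon_min, lat_seq),
    cbind(domain$lon_max, lat_seq)
  )
  pr <- proj_forward(proj, outline[, 1], outline[, 2])
  bbox <- c(
    xmin = min(pr$x), xmax = max(pr$x),
    ymin = min(pr$y), ymax = max(pr$y)
  )

  # candidate lattice range: hexagon half-height = side, half-width = w/2
  w2 <- sqrt(3) * side / 2
  r_rng <- floor((bbox["ymin"] - side) / (1.5 * side)):
    ceiling((bbox["ymax"] + side) / (1.5 * side))
  cand <- purrr::map_dfr(r_rng, function(r) {
    q_lo <- floor((bbox["xmin"] - w2) / (sqrt(3) * side) - r / 2)
    q_hi <- ceiling((bbox["xmax"] + w2) / (sqrt(3) * side) - r / 2)
    tibble::tibble(q = q_lo:q_hi, r = r)
  })
  cand$x <- sqrt(3) * side * (cand$q + cand$r / 2)
  cand$y <- 1.5 * side * cand$r

  keep <- vapply(
    seq_len(nrow(cand)),
    function(i) {
      hex_intersects_rect(cand$x[i], cand$y[i], side,
                          bbox["xmin"], bbox["xmax"],
                          bbox["ymin"], bbox["ymax"])
    },
    logical(1)
  )
  cells <- cand[keep, , drop = FALSE]
  cells <- dplyr::arrange(cells, .data$r, .data$q)
  cells$cell <- seq_len(nrow(cells))
  ll <- proj_inverse(proj, cells$x, cells$y)
  cells$lon <- ll$lon
  cells$lat <- ll$lat
  cells$ocean <- TRUE
  cells <- dplyr::select(
    cells, "cell", "q", "r", "x", "y", "lon", "lat", "ocean"
  )

  structure(
    list(
      cells = cells,
      side_km = side,
      circumdiameter_km = circumdiameter_km,
      proj = proj,
      domain = domain,
      bbox_km = bbox
    ),
    class = "hex_grid"
  )
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf(
    "hex_grid: %d cells, circumdiameter %g km (side %g km), area %.2f km2/cell\n",
    nrow(x$cells), x$circumdiameter_km, x$side_km, hex_cell_area_km2(x)
  ))
  cat(sprintf(
    "  domain lon [%g, %g], lat [%g, %g]; %d ocean cells\n",
    x$domain$lon_min, x$domain$lon_max, x$domain$lat_min, x$domain$lat_max,
    sum(x$cells$ocean)
  ))
  invisible(x)
}

#' Projected area of one grid cell (closed form)
#'
#' Regular hexagon with side \eqn{s}: area \eqn{(3\sqrt{3}/2) s^2}. All cells
#' of a `hex_grid` share this projected area exactly (equal-area property).
#'
#' @param grid A `hex_grid`.
#' @return Area in km^2.
#' @export
hex_cell_area_km2 <- function(grid) {
  stopifnot(inherits(grid, "hex_grid"))
  3 * sqrt(3) / 2 * grid$side_km^2
}

# pointy-top hexagon vertex offsets (unit circumradius), anticlockwise from
# 30 degrees; includes the top (90) and bottom (270) points
hex_unit_vertices <- function() {
  ang <- (30 + 60 * 0:5) * pi / 180
  cbind(cos(ang), sin(ang))
}

# separating-axis test: regular pointy-top hexagon (centre cx,cy, side s)
# vs axis-aligned rectangle; touching counts as intersecting
hex_intersects_rect <- function(cx, cy, s, xmin, xmax, ymin, ymax, tol = 1e-9) {
  v <- hex_unit_vertices() * s
  hx <- cx + v[, 1]
  hy <- cy + v[, 2]
  rx <- c(xmin, xmax, xmax, xmin)
  ry <- c(ymin, ymin, ymax, ymax)
  # axes: rectangle normals + hexagon edge normals (3 unique directions)
  axes <- rbind(
    c(1, 0), c(0, 1),
    t(vapply(1:3, function(k) {
      ex <- hx[k + 1] - hx[k]
      ey <- hy[k + 1] - hy[k]
      n <- c(-ey, ex)
      n / sqrt(sum(n^2))
    }, numeric(2)))
  )
  for (i in seq_len(nrow(axes))) {
    a <- axes[i, ]
    p1 <- hx * a[1] + hy * a[2]
    p2 <- rx * a[1] + ry * a[2]
    if (max(p1) < min(p2) - tol || max(p2) < min(p1) - tol) return(FALSE)
  }
  TRUE
}

#' Assign lon/lat points to grid cells
#'
#' Projects each point and resolves its hexagon by cube-rounding of the
#' fractional axial lattice coordinates. Points whose hexagon is not part of
#' the grid (outside the tiled domain) get `NA`. Points exactly on a cell
#' boundary resolve deterministically via the lattice rounding rule
#' (a measure-zero set).
#'
#' @param grid A `hex_grid`.
#' @param lon,lat Numeric vectors, degrees.
#' @return Integer vector of cell ids (`NA` outside the tiling).
#' @export
locate_points <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "hex_grid"), length(lon) == length(lat))
  if (length(lon) == 0) return(integer(0))
  if (any(!is.finite(lon) | !is.finite(lat))) {
    stop("locate_points requires finite coordinates")
  }
  p <- proj_forward(grid$proj, lon, lat)
  s <- grid$side_km
  rf <- p$y / (1.5 * s)
  qf <- p$x / (sqrt(3) * s) - rf / 2
  ax <- axial_round(qf, rf)
  key <- paste(ax$q, ax$r)
  idx <- match(key, paste(grid$cells$q, grid$cells$r))
  grid$cells$cell[idx]
}

# cube-coordinate rounding of fractional axial coordinates (standard
# hexagonal lattice quantisation)
axial_round <- function(qf, rf) {
  xf <- qf
  zf <- rf
  yf <- -xf - zf
  rx <- round(xf)
  ry <- round(yf)
  rz <- round(zf)
  dx <- abs(rx - xf)
  dy <- abs(ry - yf)
  dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

#' Vertex rings of grid cells
#'
#' @param grid A `hex_grid`.
#' @param cells Optional integer vector of cell ids (default: all).
#' @return Tibble with `cell`, `vertex` (1-6, anticlockwise), projected
#'   `x`, `y` (km) and `lon`, `lat` (degrees).
#' @export
hex_vertices <- function(grid, cells = NULL) {
  stopifnot(inherits(grid, "hex_grid"))
  cc <- grid$cells
  if (!is.null(cells)) cc <- cc[match(cells, cc$cell), , drop = FALSE]
  v <- hex_unit_vertices() * grid$side_km
  out <- tidyr::crossing(cell = cc$cell, vertex = 1:6)
  out <- dplyr::arrange(out, .data$cell, .data$vertex)
  i <- match(out$cell, cc$cell)
  out$x <- cc$x[i] + v[out$vertex, 1]
  out$y <- cc$y[i] + v[out$vertex, 2]
  ll <- proj_inverse(grid$proj, out$x, out$y)
  out$lon <- ll$lon
  out$lat <- ll$lat
  out
}

#' Flag land cells using a land polygon
#'
#' Cells whose centre (lon/lat) falls inside `land` are marked `ocean = FALSE`
#' and are excluded from null-usage surfaces and model design tables. This
#' masking stands in for a boundary-respecting smoother: the spatial term is
#' fitted and evaluated only on ocean cells.
#'
#' @param grid A `hex_grid`.
#' @param land A `region_polygon` (see [region_polygon()]) describing land.
#' @return The grid with an updated `ocean` flag.
#' @export
set_ocean_mask <- function(grid, land) {
  stopifnot(inherits(grid, "hex_grid"))
  on_land <- point_in_region(land, grid$cells$lon, grid$cells$lat)
  grid$cells$ocean <- !on_land
  grid
}

#' Export / import grid cells as GeoJSON
#'
#' `write_grid_geojson()` writes one Polygon feature per cell with
#' properties `cell`, `q`, `r`, `x`, `y`, `ocean`, plus the grid's
#' projection and geometry settings as foreign members so
#' `read_grid_geojson()` can rebuild the `hex_grid` object exactly.
#'
#' @param grid A `hex_grid`.
#' @param path File path.
#' @return `read_grid_geojson()` returns a `hex_grid`.
#' @export
write_grid_geojson <- function(grid, path) {
  stopifnot(inherits(grid, "hex_grid"))
  verts <- hex_vertices(grid)
  feats <- lapply(seq_len(nrow(grid$cells)), function(i) {
    cc <- grid$cells[i, ]
    vv <- verts[verts$cell == cc$cell, , drop = FALSE]
    ring <- lapply(c(seq_len(6), 1), function(k) c(vv$lon[k], vv$lat[k]))
    list(
      type = "Feature",
      properties = list(cell = cc$cell, q = cc$q, r = cc$r,
                        x = cc$x, y = cc$y, ocean = cc$ocean),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  gj <- list(
    type = "FeatureCollection",
    hexrich_grid = list(
      circumdiameter_km = grid$circumdiameter_km,
      proj = list(lon0 = grid$proj$lon0, lat0 = grid$proj$lat0),
      domain = grid$domain,
      bbox_km = as.list(grid$bbox_km)
    ),
    features = feats
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_geojson
#' @export
read_grid_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  meta <- gj$hexrich_grid
  if (is.null(meta)) stop("not a hexrich grid GeoJSON (missing metadata)")
  props <- lapply(gj$features, `[[`, "properties")
  cells <- tibble::tibble(
    cell = vapply(props, function(p) as.integer(p$cell), integer(1)),
    q = vapply(props, function(p) as.integer(p$q), integer(1)),
    r = vapply(props, function(p) as.integer(p$r), integer(1)),
    x = vapply(props, function(p) as.numeric(p$x), numeric(1)),
    y = vapply(props, function(p) as.numeric(p$y), numeric(1)),
    ocean = vapply(props, function(p) isTRUE(p$ocean), logical(1))
  )
  proj <- laea_projection(meta$proj$lon0, meta$proj$lat0)
  ll <- proj_inverse(proj, cells$x, cells$y)
  cells$lon <- ll$lon
  cells$lat <- ll$lat
  cells <- cells[, c("cell", "q", "r", "x", "y", "lon", "lat", "ocean")]
  structure(
    list(
      cells = cells,
      side_km = meta$circumdiameter_km / 2,
      circumdiameter_km = meta$circumdiameter_km,
      proj = proj,
      domain = meta$domain,
      bbox_km = unlist(meta$bbox_km)
    ),
    class = "hex_grid"
  )
}
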