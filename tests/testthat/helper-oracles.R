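# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by different algorithms than the
# package (winding number vs ray casting, polygon clipping vs separating
# axes, nearest-centre search vs lattice rounding).

# winding-number point-in-polygon (single ring, non-zero rule; for the
# convex / simple test polygons used here it agrees with even-odd)
winding_inside <- function(ring, px, py) {
  n <- nrow(ring)
  vapply(seq_along(px), function(i) {
    wn <- 0
    for (e in seq_len(n)) {
      x1 <- ring[e, 1]; y1 <- ring[e, 2]
      x2 <- ring[e %% n + 1, 1]; y2 <- ring[e %% n + 1, 2]
      if (y1 <= py[i]) {
        if (y2 > py[i] &&
            (x2 - x1) * (py[i] - y1) - (px[i] - x1) * (y2 - y1) > 0) {
          wn <- wn + 1
        }
      } else if (y2 <= py[i] &&
                 (x2 - x1) * (py[i] - y1) - (px[i] - x1) * (y2 - y1) < 0) {
        wn <- wn - 1
      }
    }
    wn != 0
  }, logical(1))
}

# Sutherland-Hodgman clip of a convex polygon by an axis-aligned rectangle,
# plus shoelace area, used as the tiling-count oracle
clip_area <- function(poly_x, poly_y, xmin, xmax, ymin, ymax) {
  clip_halfplane <- function(px, py, keep, intersect) {
    if (length(px) == 0) return(list(x = numeric(0), y = numeric(0)))
    nx <- c(); ny <- c()
    n <- length(px)
    for (i in seq_len(n)) {
      j <- i %% n + 1
      pi_in <- keep(px[i], py[i])
      pj_in <- keep(px[j], py[j])
      if (pi_in) { nx <- c(nx, px[i]); ny <- c(ny, py[i]) }
      if (pi_in != pj_in) {
        it <- intersect(px[i], py[i], px[j], py[j])
        nx <- c(nx, it[1]); ny <- c(ny, it[2])
      }
    }
    list(x = nx, y = ny)
  }
  p <- list(x = poly_x, y = poly_y)
  p <- clip_halfplane(p$x, p$y, function(x, y) x >= xmin, function(x1, y1, x2, y2) {
    t <- (xmin - x1) / (x2 - x1); c(xmin, y1 + t * (y2 - y1))
  })
  p <- clip_halfplane(p$x, p$y, function(x, y) x <= xmax, function(x1, y1, x2, y2) {
    t <- (xmax - x1) / (x2 - x1); c(xmax, y1 + t * (y2 - y1))
  })
  p <- clip_halfplane(p$x, p$y, function(x, y) y >= ymin, function(x1, y1, x2, y2) {
    t <- (ymin - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ymin)
  })
  p <- clip_halfplane(p$x, p$y, function(x, y) y <= ymax, function(x1, y1, x2, y2) {
    t <- (ymax - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ymax)
  })
  if (length(p$x) < 3) return(0)
  n <- length(p$x)
  abs(sum(p$x * p$y[c(2:n, 1)] - p$x[c(2:n, 1)] * p$y)) / 2
}

shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# build a tracks tibble from per-fix vectors (one individual by default)
make_track <- function(lon, lat, id = "bird1", species = "sp1",
                       colony = "col1", start = "2008-12-01") {
  n <- length(lon)
  tibble::tibble(
    individual_id = id, species = species, colony = colony,
    timestamp = as.POSIXct(start, tz = "UTC") + seq_len(n) * 43200,
    lon = lon, lat = lat
  )
}

# a compact study configuration for fast simulation-based tests
tiny_config <- function(seed = 1, n = 3, winter = 60, p_visit = 1,
                        p_region_time = 0.9) {
  sp <- tibble::tibble(
    species = c("northern gannet", "common tern", "Cory's shearwater"),
    colony = c("a", "b", "c"),
    colony_lon = c(-9, 0, -25.5),
    colony_lat = c(48, 47, 37.8),
    n_individuals = n,
    winter_mean = winter,
    winter_sd = 5,
    p_visit_region = p_visit,
    p_region_time = p_region_time,
    step_km = 120,
    attraction = 0.25
  )
  study_config(
    species = sp,
    domain = list(lon_min = -45, lon_max = 5, lat_min = -10, lat_max = 50),
    seed = seed
  )
}

square_region <- function(lon0 = -20, lon1 = -10, lat0 = 10, lat1 = 20,
                          name = "box") {
  region_polygon(name, cbind(c(lon0, lon1, lon1, lon0),
                             c(lat0, lat0, lat1, lat1)))
}
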