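test_that("projection round-trips and maps its centre to the origin", {
  p <- laea_projection()
  expect_equal(as.numeric(proj_forward(p, -15, 0)), c(0, 0))
  set.seed(1)
  lon <- runif(200, -179, 179)
  lat <- runif(200, -85, 85)
  xy <- proj_forward(p, lon, lat)
  ll <- proj_inverse(p, xy$x, xy$y)
  expect_equal(ll$lon, lon, tolerance = 1e-9)
  expect_equal(ll$lat, lat, tolerance = 1e-9)
})

test_that("200 km cells have the closed-form area and lattice spacing", {
  g <- build_hex_grid(list(lon_min = -20, lon_max = -10,
                           lat_min = 0, lat_max = 10))
  expect_equal(hex_cell_area_km2(g), 3 * sqrt(3) / 2 * 100^2)
  # same-row centres sit sqrt(3) * side apart
  row0 <- g$cells[g$cells$r == g$cells$r[1], ]
  expect_equal(diff(sort(row0$x))[1], sqrt(3) * 100)
  # every cell's vertex ring has the same shoelace area (equal-area tiling)
  verts <- hex_vertices(g)
  areas <- vapply(split(verts, verts$cell), function(v) {
    shoelace_area(v$x, v$y)
  }, numeric(1))
  expect_equal(max(areas) / min(areas), 1)
  expect_equal(unname(areas[1]), hex_cell_area_km2(g), tolerance = 1e-9)
})

test_that("cell count over a 10x10 degree box matches a clipping oracle", {
  domain <- list(lon_min = -20, lon_max = -10, lat_min = -5, lat_max = 5)
  g <- build_hex_grid(domain)
  # oracle: enumerate a generous lattice window and keep hexagons whose
  # clipped intersection with the projected bbox has positive area
  bb <- g$bbox_km
  s <- g$side_km
  count <- 0
  for (r in seq(floor((bb["ymin"] - 2 * s) / (1.5 * s)),
                ceiling((bb["ymax"] + 2 * s) / (1.5 * s)))) {
    for (q in seq(floor((bb["xmin"] - 2 * s) / (sqrt(3) * s) - r / 2),
                  ceiling((bb["xmax"] + 2 * s) / (sqrt(3) * s) - r / 2))) {
      cx <- sqrt(3) * s * (q + r / 2)
      cy <- 1.5 * s * r
      ang <- (30 + 60 * 0:5) * pi / 180
      a <- clip_area(cx + s * cos(ang), cy + s * sin(ang),
                     bb["xmin"], bb["xmax"], bb["ymin"], bb["ymax"])
      if (a > 1e-6) count <- count + 1
    }
  }
  expect_equal(nrow(g$cells), count)
})

test_that("locate_points agrees with a brute-force nearest-centre oracle", {
  domain <- list(lon_min = -30, lon_max = -10, lat_min = 5, lat_max = 25)
  g <- build_hex_grid(domain)
  set.seed(42)
  lon <- runif(1000, domain$lon_min, domain$lon_max)
  lat <- runif(1000, domain$lat_min, domain$lat_max)
  got <- locate_points(g, lon, lat)
  expect_false(anyNA(got)) # partition: every in-domain point has a cell
  p <- proj_forward(g$proj, lon, lat)
  oracle <- vapply(seq_along(lon), function(i) {
    g$cells$cell[which.min((g$cells$x - p$x[i])^2 + (g$cells$y - p$y[i])^2)]
  }, integer(1))
  expect_identical(got, oracle)
})

test_that("cell centres locate to their own cell; far points to none", {
  g <- build_hex_grid(list(lon_min = -20, lon_max = -10,
                           lat_min = 0, lat_max = 10))
  expect_identical(locate_points(g, g$cells$lon, g$cells$lat), g$cells$cell)
  expect_true(is.na(locate_points(g, 150, -70)))
  expect_error(locate_points(g, NaN, 0), "finite")
})

test_that("grid construction rejects degenerate or polar domains", {
  expect_error(build_hex_grid(list(lon_min = 0, lon_max = 0,
                                   lat_min = 0, lat_max = 1)), "degenerate")
  expect_error(build_hex_grid(list(lon_min = 0, lon_max = 10,
                                   lat_min = 80, lat_max = 90)), "pole")
  expect_error(build_hex_grid(list(lon_min = 0, lon_max = 10,
                                   lat_min = 0, lat_max = 10),
                              circumdiameter_km = 0), "positive")
})

test_that("grid ids are stable and GeoJSON round-trips the grid", {
  domain <- list(lon_min = -20, lon_max = -10, lat_min = 0, lat_max = 10)
  g1 <- build_hex_grid(domain)
  g2 <- build_hex_grid(domain)
  expect_identical(g1$cells, g2$cells)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_grid_geojson(g1, path)
  g3 <- read_grid_geojson(path)
  expect_equal(g3$cells$cell, g1$cells$cell)
  expect_equal(g3$cells$x, g1$cells$x, tolerance = 1e-9)
  expect_equal(g3$cells$ocean, g1$cells$ocean)
  expect_equal(g3$circumdiameter_km, g1$circumdiameter_km)
})

test_that("ocean mask flags cells with centre on land", {
  g <- build_hex_grid(list(lon_min = -20, lon_max = -10,
                           lat_min = 0, lat_max = 10))
  land <- square_region(-16, -10, 0, 10, name = "land")
  gm <- set_ocean_mask(g, land)
  on_land <- point_in_region(land, gm$cells$lon, gm$cells$lat)
  expect_identical(gm$cells$ocean, !on_land)
  expect_true(any(!gm$cells$ocean) && any(gm$cells$ocean))
})
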