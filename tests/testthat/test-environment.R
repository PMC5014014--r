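toy_field <- function(vals, month = NULL, year = NULL) {
  env_field("sst", "degC", lon = c(0.5, 1.5), lat = c(10.5, 11.5),
            values = matrix(vals, 2, 2), month = month, year = year)
}

test_that("seasonal climatology averages slices and propagates missingness", {
  # constant slices -> identity
  slices <- list(toy_field(rep(18, 4), 12, 2002), toy_field(rep(18, 4), 1, 2003))
  comp <- seasonal_climatology(slices, months = c(12, 1, 2, 3), years = 2002)
  expect_equal(comp$values, matrix(18, 2, 2))

  # toy 2x2 raster, two seasons x four months: per-pixel mean equals the
  # hand-computed average of the 8 slices
  vals <- lapply(1:8, function(i) matrix(i + (1:4) / 10, 2, 2))
  slices <- list(
    toy_field(vals[[1]], 12, 2002), toy_field(vals[[2]], 1, 2003),
    toy_field(vals[[3]], 2, 2003), toy_field(vals[[4]], 3, 2003),
    toy_field(vals[[5]], 12, 2003), toy_field(vals[[6]], 1, 2004),
    toy_field(vals[[7]], 2, 2004), toy_field(vals[[8]], 3, 2004)
  )
  comp <- seasonal_climatology(slices, months = c(12, 1, 2, 3),
                               years = 2002:2003)
  expected <- Reduce(`+`, vals) / 8
  expect_equal(comp$values, expected)

  # a pixel missing in every slice stays missing; partially missing uses
  # the available slices only
  m1 <- matrix(c(NA, 2, 3, 4), 2, 2)
  m2 <- matrix(c(NA, 6, NA, 8), 2, 2)
  comp <- seasonal_climatology(list(toy_field(m1, 12, 2002),
                                    toy_field(m2, 1, 2003)),
                               months = c(12, 1, 2, 3), years = 2002)
  expect_true(is.na(comp$values[1, 1]))
  expect_equal(comp$values[2, 1], 4)
  expect_equal(comp$values[1, 2], 3)
})

test_that("the winter window spans the year boundary correctly", {
  dec02 <- toy_field(rep(1, 4), 12, 2002)
  mar03 <- toy_field(rep(3, 4), 3, 2003)
  mar02 <- toy_field(rep(100, 4), 3, 2002) # belongs to season 2001
  comp <- seasonal_climatology(list(dec02, mar03, mar02),
                               months = c(12, 1, 2, 3), years = 2002)
  expect_equal(comp$values, matrix(2, 2, 2)) # mar02 excluded
  expect_error(
    seasonal_climatology(list(mar02), months = c(12, 1, 2, 3), years = 2005),
    "no slices"
  )
})

test_that("cell covariates average pixels inside each hexagon", {
  grid <- build_hex_grid(list(lon_min = -25, lon_max = -5,
                              lat_min = 5, lat_max = 25))
  lon <- seq(-29.75, -0.25, by = 0.5)
  lat <- seq(0.25, 29.75, by = 0.5)
  const18 <- env_field("sst", "degC", lon, lat,
                       matrix(18, length(lon), length(lat)))
  chl1 <- env_field("chl", "mg m-3", lon, lat,
                    matrix(1, length(lon), length(lat)))
  covs <- cell_covariates(grid, const18, chl1)
  expect_true(all(covs$sst_mean == 18))
  expect_true(all(covs$chl_log10 == 0)) # log10(1)
  expect_equal(nrow(covs), nrow(grid$cells))

  # linear gradient 0.1 degC per degree lon: cell mean equals the gradient
  # at the centroid of contributing pixel centres (independent enumeration)
  grad <- env_field("sst", "degC", lon, lat,
                    outer(0.1 * lon, rep(1, length(lat))))
  covs_g <- cell_covariates(grid, grad, chl1)
  px <- expand.grid(lon = lon, lat = lat)
  px$cell <- locate_points(grid, px$lon, px$lat)
  expected <- tapply(0.1 * px$lon, px$cell, mean)
  got <- covs_g$sst_mean[match(as.integer(names(expected)), covs_g$cell)]
  expect_equal(got, as.numeric(expected), tolerance = 1e-6)
  # cell means bounded by contributing pixel range
  expect_true(all(covs_g$sst_mean >= min(0.1 * lon) &
                    covs_g$sst_mean <= max(0.1 * lon)))
})

test_that("cells without valid pixels are dropped with a count", {
  grid <- build_hex_grid(list(lon_min = -25, lon_max = -5,
                              lat_min = 5, lat_max = 25))
  lon <- seq(-29.75, -0.25, by = 0.5)
  lat <- seq(0.25, 29.75, by = 0.5)
  vals <- matrix(18, length(lon), length(lat))
  vals[lon < -15, ] <- NA # kill the western half
  sst <- env_field("sst", "degC", lon, lat, vals)
  chl <- env_field("chl", "mg m-3", lon, lat,
                   matrix(1, length(lon), length(lat)))
  covs <- cell_covariates(grid, sst, chl)
  expect_gt(attr(covs, "n_dropped"), 0)
  expect_false(any(is.na(covs$sst_mean)))
})

test_that("env fields round-trip through netCDF", {
  lon <- seq(-19.5, -10.5, by = 1)
  lat <- seq(10.5, 19.5, by = 1)
  vals <- matrix(rnorm(100), 10, 10)
  vals[3, 7] <- NA
  f <- env_field("chl", "mg m-3", lon, lat, vals, month = 12, year = 2006)
  path <- withr::local_tempfile(fileext = ".nc")
  write_env_nc(f, path)
  f2 <- read_env_nc(path)
  expect_equal(f2$var, "chl")
  expect_equal(f2$units, "mg m-3")
  expect_equal(f2$lon, lon)
  expect_equal(f2$values, vals, tolerance = 1e-12)
  expect_equal(f2$month, 12L)
  expect_equal(f2$year, 2006L)
})
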