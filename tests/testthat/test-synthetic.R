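test_that("simulation is seed-deterministic", {
  s1 <- simulate_study(tiny_config(seed = 3))
  s2 <- simulate_study(tiny_config(seed = 3))
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sst$values, s2$sst$values)
  s3 <- simulate_study(tiny_config(seed = 4))
  expect_false(identical(s1$tracks, s3$tracks))
})

test_that("fix counts follow cadence, winter length and equinox gaps", {
  # no equinox gap, fixed winter length: exactly winter * cadence fixes
  cfg <- tiny_config(seed = 2, n = 2, winter = 100)
  cfg$equinox_gap_days <- 0
  cfg$species$winter_sd <- 0
  sim <- simulate_tracks(cfg)
  expect_true(all(sim$truth$n_fixes == 200))
  # with the gap, dropped fixes are exactly those in the equinox windows
  cfg2 <- tiny_config(seed = 2, n = 2, winter = 200)
  cfg2$species$winter_sd <- 0
  sim2 <- simulate_tracks(cfg2)
  n_all <- 400
  start <- as.POSIXct("2008-11-01", tz = "UTC")
  ts_full <- start + seq_len(n_all) * 43200
  yd <- as.POSIXlt(ts_full)$yday + 1
  dropped <- sum(pmin(abs(yd - 80), 365 - abs(yd - 80)) <= 10 |
                   pmin(abs(yd - 266), 365 - abs(yd - 266)) <= 10)
  expect_true(all(sim2$truth$n_fixes == n_all - dropped))
  expect_gt(dropped, 0)
})

test_that("all fixes stay inside the domain box", {
  st <- simulate_study(tiny_config(seed = 6, n = 4))
  dm <- st$config$domain
  expect_true(all(st$tracks$lon >= dm$lon_min & st$tracks$lon <= dm$lon_max))
  expect_true(all(st$tracks$lat >= dm$lat_min & st$tracks$lat <= dm$lat_max))
})

test_that("truth flags are consistent with pre-error positions", {
  st <- simulate_study(tiny_config(seed = 7, n = 4))
  by_id <- split(st$tracks, st$tracks$individual_id)
  for (id in names(by_id)) {
    tr <- by_id[[id]]
    in_reg <- point_in_region(st$region, tr$true_lon, tr$true_lat)
    row <- st$truth[st$truth$individual_id == id, ]
    expect_equal(row$visited_true, any(in_reg))
    expect_equal(row$prop_true, mean(in_reg))
  }
})

test_that("visit decisions track p_visit_region and saturate at 1", {
  # p = 1 with centroids well inside the region: nearly all individuals
  # have at least one true fix inside (Monte-Carlo over >= 100 birds)
  cfg <- tiny_config(seed = 8, n = 40, winter = 40, p_visit = 1,
                     p_region_time = 0.9)
  sim <- simulate_tracks(cfg, sst = NULL)
  expect_gte(mean(sim$truth$visited_true), 0.95)
  expect_equal(nrow(sim$truth), 120)
  # intermediate p: empirical fraction within binomial error
  cfg2 <- tiny_config(seed = 9, n = 40, winter = 30, p_visit = 0.6)
  sim2 <- simulate_tracks(cfg2, sst = NULL)
  phat <- mean(sim2$truth$visit_intended)
  expect_lt(abs(phat - 0.6), 4 * sqrt(0.6 * 0.4 / 120))
})

test_that("simulated fields obey the generating formulas", {
  dom <- list(lon_min = -40, lon_max = 0, lat_min = 0, lat_max = 40)
  reg <- square_region(-25, -15, 10, 25)
  # zero anomaly, zero noise, zero tilt: SST equals the latitudinal
  # baseline exactly
  f0 <- simulate_env_fields(
    dom, baseline = list(sst_noise_sd = 0, sst_per_deg_lon = 0),
    upwelling = list(region = reg, sst_anomaly = 0, chl_multiplier = 1),
    seed = 1
  )
  tbl <- env_field_tbl(f0$sst)
  expect_equal(tbl$value, 28 - 0.3 * abs(tbl$lat), tolerance = 1e-12)
  # anomaly -4: masked mean inside the polygon is ~4 degC below the
  # same-latitude baseline outside it
  f1 <- simulate_env_fields(
    dom, baseline = list(sst_noise_sd = 0, sst_per_deg_lon = 0),
    upwelling = list(region = reg, sst_anomaly = -4, chl_multiplier = 5),
    seed = 2
  )
  sst <- env_field_tbl(f1$sst)
  inside <- point_in_region(reg, sst$lon, sst$lat)
  same_lat <- sst$lat >= 10 & sst$lat <= 25
  diff_means <- mean(sst$value[inside]) -
    mean(sst$value[!inside & same_lat])
  expect_equal(diff_means, -4, tolerance = 0.2)
  # CHL multiplier: mean log10 CHL higher inside than outside
  chl <- env_field_tbl(f1$chl)
  expect_gt(mean(log10(chl$value[inside])),
            mean(log10(chl$value[!inside])) + 0.5)
  # configuration errors
  expect_error(simulate_env_fields(dom, resolution = 0), "resolution")
  expect_error(simulate_env_fields(
    dom, upwelling = list(region = reg, sst_anomaly = 2)), "anomaly")
})

test_that("land masking removes field pixels and wintering habitat", {
  st <- simulate_study(tiny_config(seed = 11, n = 2))
  land <- st$land
  tbl <- env_field_tbl(st$sst)
  on_land <- point_in_region(land, tbl$lon, tbl$lat)
  expect_true(all(is.na(tbl$value[on_land])))
  expect_true(any(!is.na(tbl$value[!on_land])))
})

test_that("location error magnitude matches its quadrature expectation", {
  cfg <- tiny_config(seed = 12, n = 30, winter = 90)
  sim <- simulate_tracks(cfg, sst = NULL)
  tr <- sim$tracks
  # exclude fixes clamped at the domain edge, where error is truncated
  dm <- cfg$domain
  interior <- tr$lon > dm$lon_min + 3 & tr$lon < dm$lon_max - 3 &
    tr$lat > dm$lat_min + 5 & tr$lat < dm$lat_max - 5 &
    tr$true_lon > dm$lon_min + 3 & tr$true_lon < dm$lon_max - 3 &
    tr$true_lat > dm$lat_min + 5 & tr$true_lat < dm$lat_max - 5
  tr <- tr[interior, ]
  expect_gt(nrow(tr), 1e4)
  d_obs <- geosphere::distHaversine(cbind(tr$true_lon, tr$true_lat),
                                    cbind(tr$lon, tr$lat), r = 6371.0088)
  # oracle: E[sqrt((a Z1)^2 + (b Z2)^2)] by 2-D Gauss-Legendre quadrature
  # over the standard normal, at the mean absolute latitude of the fixes
  km_per_deg <- 6371.0088 * pi / 180
  a <- 0.7 * km_per_deg * mean(cos(tr$true_lat * pi / 180))
  b <- 1.5 * km_per_deg
  gl <- seq(-6, 6, length.out = 301)
  w <- dnorm(gl) * (gl[2] - gl[1])
  expected <- sum(outer(w, w) * sqrt(outer((a * gl)^2, (b * gl)^2, `+`)))
  expect_lt(abs(mean(d_obs) - expected) / expected, 0.05)
})
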