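test_that("vif is exact on orthogonal designs and flags collinearity", {
  d <- data.frame(a = c(-1, -1, 1, 1), b = c(-1, 1, -1, 1))
  v <- vif(d, c("a", "b"))
  expect_equal(v$vif, c(1, 1))
  # near-duplicate covariate
  set.seed(8)
  x <- rnorm(200)
  d2 <- data.frame(x = x, x2 = x + rnorm(200, 0, 1e-3), z = rnorm(200))
  v2 <- vif(d2, c("x", "x2", "z"))
  expect_gt(max(v2$vif[1:2]), 100)
  # exact collinearity reports Inf, not an error
  d3 <- data.frame(x = x, y = 2 * x)
  expect_true(is.infinite(vif(d3, c("x", "y"))$vif[1]))
})

test_that("vif matches the car package on a random design", {
  set.seed(9)
  d <- as.data.frame(matrix(rnorm(300), 100, 3))
  names(d) <- c("a", "b", "c")
  d$a <- d$a + 0.6 * d$b
  d$y <- rnorm(100)
  ours <- vif(d, c("a", "b", "c"))
  theirs <- car::vif(lm(y ~ a + b + c, data = d))
  expect_equal(ours$vif, unname(theirs[ours$covariate]), tolerance = 1e-8)
})

test_that("a penalized smooth recovers sin(x) within RMSE 0.1", {
  set.seed(10)
  n <- 200
  x <- runif(n, 0, 2 * pi)
  y <- sin(x) + rnorm(n, 0, 0.1)
  fit <- fit_penalized_am(tibble::tibble(y = y, x = x), "y", smooth_1d = "x")
  grid_x <- seq(min(x), max(x), length.out = 500)
  pred <- as.numeric(mgcv::predict.gam(fit$gam,
                                       newdata = data.frame(x = grid_x)))
  rmse <- sqrt(mean((pred - sin(grid_x))^2))
  expect_lt(rmse, 0.1)
})

test_that("a structureless response yields a flat fit with no smooth effects", {
  set.seed(12)
  d <- tibble::tibble(y = 5 + rnorm(100, 0, 1e-6), x = runif(100),
                      z = runif(100))
  fit <- fit_penalized_am(d, "y", smooth_1d = c("x", "z"))
  expect_equal(unname(fitted(fit$gam)), rep(5, 100), tolerance = 1e-4)
  tm <- mgcv::predict.gam(fit$gam, type = "terms")
  expect_lt(max(abs(tm)), 1e-4)
  expect_lte(fit$adj_r2, 0.2)
})

test_that("smoothing-parameter limits bracket the fit", {
  set.seed(13)
  n <- 60
  x <- seq(0, 1, length.out = n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.2)
  d <- tibble::tibble(y = y, x = x)
  # sp -> infinity collapses the smooth to its linear null space
  f_inf <- fit_penalized_am(d, "y", smooth_1d = "x", sp = 1e9)
  lin <- lm(y ~ x)
  expect_equal(unname(fitted(f_inf$gam)), unname(fitted(lin)),
               tolerance = 1e-3)
  # sp -> 0 uses (almost) the full basis and fits tighter than the default
  f0 <- fit_penalized_am(d, "y", smooth_1d = "x", sp = 0)
  f_def <- fit_penalized_am(d, "y", smooth_1d = "x")
  expect_gt(sum(f0$gam$edf), 9.5)
  expect_lte(sum(residuals(f0$gam)^2), sum(residuals(f_def$gam)^2) + 1e-10)
})

test_that("unpenalized log-likelihood is monotone over nested term sets", {
  set.seed(14)
  n <- 150
  d <- tibble::tibble(x = runif(n), z = runif(n))
  d$y <- sin(2 * pi * d$x) + rnorm(n, 0, 0.3)
  small <- fit_penalized_am(d, "y", smooth_1d = "x", sp = c(0))
  large <- fit_penalized_am(d, "y", smooth_1d = c("x", "z"), sp = c(0, 0))
  expect_gte(as.numeric(logLik(large$gam)), as.numeric(logLik(small$gam)))
})

test_that("smooth_peak finds a quadratic optimum and boundary maxima", {
  set.seed(15)
  n <- 300
  x <- runif(n, 10, 25)
  d <- tibble::tibble(x = x, y = -(x - 17.5)^2 / 10 + rnorm(n, 0, 0.3))
  fit <- fit_penalized_am(d, "y", smooth_1d = "x")
  pk <- smooth_peak(fit, "x")
  expect_lt(abs(pk$peak - 17.5), 0.5)
  expect_true(pk$lower <= pk$peak && pk$peak <= pk$upper)
  expect_true(pk$interior)
  # monotone-increasing truth: argmax at the upper end of the range
  d2 <- tibble::tibble(x = x, y = 0.3 * x + rnorm(n, 0, 0.3))
  fit2 <- fit_penalized_am(d2, "y", smooth_1d = "x")
  pk2 <- smooth_peak(fit2, "x")
  expect_gt(pk2$peak, quantile(x, 0.95))
  expect_error(smooth_peak(fit, "z"), "not a fitted")
})

test_that("select_model returns a well-formed AIC ranking", {
  set.seed(16)
  st <- simulate_study(tiny_config(seed = 16, n = 4, winter = 50))
  grid <- set_ocean_mask(build_hex_grid(tiny_config()$domain), st$land)
  rich <- relative_richness(occupancy(st$tracks, grid), grid)
  cols <- data.frame(lon = -9, lat = 48, n_tracked = 12,
                     range_scale_km = 1500)
  ns <- accessibility_surface(grid, cols)
  design <- dplyr::inner_join(cell_covariates(grid, st$sst, st$chl, ns),
                              rich[, c("cell", "richness")], by = "cell")
  # single candidate: one row, delta 0
  m1 <- select_model(design, candidates = "sst")
  expect_equal(nrow(m1), 1)
  expect_equal(m1$delta_aic, 0)
  expect_true(m1$retained)
  # two candidates: structural postconditions of the ranking
  m2 <- select_model(design, candidates = c("sst", "xy"))
  full <- attr(m2, "full_table")
  expect_lte(nrow(full), 3)
  expect_equal(full$delta_aic[1], 0)
  expect_true(all(diff(full$aic) >= 0))
  expect_equal(full$rank, seq_len(nrow(full)))
  expect_equal(sum(full$retained), 1)
  # the retained model is the most parsimonious within 2 AIC of the best
  cand <- full[full$delta_aic <= 2, ]
  expect_equal(full$terms[full$retained],
               cand$terms[which.min(cand$df)])
})

test_that("residual variograms separate iid noise from spatial trend", {
  set.seed(17)
  n <- 150
  x <- runif(n, 0, 2000)
  y <- runif(n, 0, 2000)
  # all-zero residuals: gamma identically zero
  v0 <- residual_variogram(rep(0, n), x, y, seed = 1)
  expect_true(all(v0$gamma[v0$n_pairs > 0] == 0))
  # a strong smooth gradient: semivariance rises and exits the envelope
  r_trend <- x / 400 + y / 600
  vt <- residual_variogram(r_trend, x, y, seed = 1)
  ok <- vt$n_pairs > 0
  # permutations destroy the trend, so the observed curve leaves the
  # envelope: low semivariance at short range, high at long range
  outside <- vt$gamma < vt$env_lo | vt$gamma > vt$env_hi
  expect_gt(sum(outside, na.rm = TRUE), 3)
  expect_gt(cor(vt$dist_mid[ok], vt$gamma[ok]), 0.9)
  # pair counts sum to n(n-1)/2 within the half-max-distance truncation
  expect_lte(sum(vt$n_pairs), n * (n - 1) / 2)
  expect_error(residual_variogram(rnorm(10), 1:10, 1:10), ">= 30")
})

test_that("tidy and glance summarise fitted models", {
  set.seed(18)
  d <- tibble::tibble(x = runif(120), z = runif(120))
  d$y <- sin(2 * pi * d$x) + rnorm(120, 0.2)
  fit <- fit_penalized_am(d, "y", smooth_1d = c("x", "z"))
  td <- tidy(fit)
  expect_setequal(td$term, c("s(x)", "s(z)"))
  expect_true(all(td$edf > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 120)
  expect_equal(gl$aic, fit$aic)
  expect_true(gl$deviance_expl >= 0 && gl$deviance_expl <= 1)
})
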