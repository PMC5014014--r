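# Seeded synthetic study generator. Emulates the statistical structure of a
# pan-Atlantic multi-colony geolocator study: twice-daily fixes with large,
# anisotropic location error and equinox gaps; per-species winter durations;
# a cool, chlorophyll-rich coastal upwelling region visited by a
# species-dependent fraction of individuals; and a truth record (pre-error
# region membership, generated SST optimum) so downstream recovery is
# measurable.

#' Configure a synthetic tracking study
#'
#' @param species Data frame, one row per species-colony cohort, columns:
#'   `species`, `colony`, `colony_lon`, `colony_lat`, `n_individuals`,
#'   `winter_mean`, `winter_sd` (days), `p_visit_region` (probability in
#'   \[0, 1\] that an individual visits the focal region at all), `step_km`
#'   (random-walk step scale, km/day), `attraction` (pull toward the
#'   current centroid, per day), and optionally `p_region_time` (mean
#'   fraction of a visiting individual's winter spent inside the region,
#'   default 0.35). A visiting individual's winter has two phases — a stint
#'   centred in the region and the remainder at a shared secondary
#'   aggregation site — so visiting can mean anything from brief staging to
#'   full-winter residence.
#' @param domain Study bounding box: `lon_min`, `lon_max`, `lat_min`,
#'   `lat_max`.
#' @param fixes_per_day Fix cadence (default 2: the two twilights of a
#'   light-logger day).
#' @param equinox_gap_days Fixes within this many days of 21 March / 23
#'   September are dropped (latitude unresolvable near equinoxes);
#'   default 10.
#' @param error_sd_lon,error_sd_lat Zero-mean Gaussian location error s.d.
#'   in degrees (defaults 0.7 and 1.5; geolocator latitude error exceeds
#'   longitude error, so `error_sd_lat >= error_sd_lon` is required).
#' @param start Where each walk begins: `"winter_range"` (default) draws the
#'   first position from the walk's stationary spread around the wintering
#'   centroid, so tracks represent the stationary winter period that the
#'   analysis window covers; `"colony"` starts at the breeding colony and
#'   so includes the migration leg.
#' @param sst_optimum Thermal optimum (degC) of non-breeding site selection:
#'   wintering centroids are sampled preferentially where SST is near this
#'   value (default 17.5), which is what generates a species-richness
#'   optimum at that temperature.
#' @param sst_niche_sd Width (degC, Gaussian s.d.) of the thermal
#'   suitability kernel (default 2).
#' @param accessibility_km Exponential decay scale (km) of colony
#'   accessibility governing which shared wintering area a non-visiting
#'   individual settles in (default 3000).
#' @param n_secondary_sites Number of secondary aggregation areas per
#'   species-colony cohort outside the focal region (default 3). Migratory
#'   seabirds concentrate in discrete productive wintering areas; each
#'   cohort's sites are drawn with the thermal-suitability weight, so
#'   different cohorts' wintering areas coincide preferentially where SST
#'   is near the optimum and multi-species richness develops repeated
#'   peaks near that temperature at spatially separated locations.
#' @param site_spread_km Gaussian scatter (km) of individual wintering
#'   centroids around their aggregation site (default 300).
#' @param region_time_conc Concentration of the Beta distribution from
#'   which a visiting individual's region-time fraction is drawn around its
#'   species mean (default 4; smaller = more between-individual variation,
#'   matching the wide spread of published per-individual proportions).
#' @param start_date First fix date (default `"2008-11-01"`).
#' @param seed Integer seed.
#' @return A `study_config` object.
#' @export
study_config <- function(species, domain,
                         fixes_per_day = 2, equinox_gap_days = 10,
                         error_sd_lon = 0.7, error_sd_lat = 1.5,
                         start = c("winter_range", "colony"),
                         sst_optimum = 17.5, sst_niche_sd = 2,
                         accessibility_km = 3000,
                         n_secondary_sites = 3, site_spread_km = 300,
                         region_time_conc = 4,
                         start_date = "2008-11-01", seed = 1) {
  start <- match.arg(start)
  stopifnot(sst_niche_sd > 0, accessibility_km > 0,
            n_secondary_sites >= 1, site_spread_km > 0,
            region_time_conc > 0)
  if (!"p_region_time" %in% names(species)) species$p_region_time <- 0.35
  stopifnot(all(species$p_region_time > 0 & species$p_region_time <= 1))
  species <- tibble::as_tibble(species)
  req <- c("species", "colony", "colony_lon", "colony_lat", "n_individuals",
           "winter_mean", "winter_sd", "p_visit_region", "step_km",
           "attraction")
  missing_cols <- setdiff(req, names(species))
  if (length(missing_cols) > 0) {
    stop("species table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(
    all(species$n_individuals >= 1),
    all(species$p_visit_region >= 0 & species$p_visit_region <= 1),
    all(species$winter_mean > 0),
    all(species$winter_sd >= 0),
    all(species$step_km > 0),
    fixes_per_day >= 1,
    equinox_gap_days >= 0,
    error_sd_lon >= 0
  )
  if (error_sd_lat < error_sd_lon) {
    stop("error_sd_lat must be >= error_sd_lon (light-logger error anisotropy)")
  }
  domain <- as.list(domain)
  structure(
    list(
      species = species, domain = domain,
      fixes_per_day = fixes_per_day, equinox_gap_days = equinox_gap_days,
      error_sd_lon = error_sd_lon, error_sd_lat = error_sd_lat,
      start = start, sst_optimum = sst_optimum, sst_niche_sd = sst_niche_sd,
      accessibility_km = accessibility_km,
      n_secondary_sites = n_secondary_sites,
      site_spread_km = site_spread_km,
      region_time_conc = region_time_conc,
      start_date = as.Date(start_date),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' Default focal upwelling region polygon
#'
#' A coastal eastern-boundary upwelling analogue off northwest Africa
#' (roughly the latitudes of the Canary Current system), abutting the
#' continent of [default_land_mass()] on its eastern edge.
#'
#' @return A `region_polygon`.
#' @export
default_upwelling_region <- function() {
  region_polygon(
    "upwelling",
    cbind(
      lon = c(-21, -13, -13, -21),
      lat = c(11, 11, 31, 31)
    )
  )
}

#' Default continental land mass
#'
#' A rectangular continent analogue directly east of the default upwelling
#' region (the north-west African coastline role): satellite fields are
#' missing over it, wintering habitat excludes it, and grid cells whose
#' centres fall on it are flagged as land and excluded from modelling.
#'
#' @return A `region_polygon`.
#' @export
default_land_mass <- function() {
  region_polygon(
    "continent",
    cbind(
      lon = c(-13, 25, 25, -13),
      lat = c(7, 7, 42, 42)
    )
  )
}

#' Full-scale default study configuration
#'
#' Eight seabird species from 12 colonies spanning 75 N to 62 S, 123
#' individuals in total, with cohort sizes, winter-period distributions and
#' region-visit probabilities patterned on published multi-colony tracking
#' summaries (see `atlantic_tracking_summary()`).
#'
#' @param seed Integer seed.
#' @return A `study_config`.
#' @export
default_study_config <- function(seed = 1) {
  sp <- tibble::tribble(
    ~species, ~colony, ~colony_lon, ~colony_lat, ~n_individuals,
    ~winter_mean, ~winter_sd, ~p_visit_region, ~p_region_time,
    "lesser black-backed gull", "north sea",      0.5,  53.5,  7, 208, 27, 0.714, 0.13,
    "northern gannet",          "celtic sea",   -10.0,  51.5, 17,  94, 13, 0.588, 0.44,
    "northern gannet",          "north atlantic", -2.0, 49.5, 17,  94, 13, 0.588, 0.44,
    "great skua",               "shetland",      -1.2,  60.2, 16,  92, 15, 0.25,  0.48,
    "Cory's shearwater",        "azores",       -25.5,  37.8, 10, 134, 30, 0.579, 0.17,
    "Cory's shearwater",        "canaries",     -16.5,  28.2,  9, 134, 30, 0.579, 0.17,
    "Scopoli's shearwater",     "balearics",      3.0,  39.5,  9, 105, 41, 1,     0.35,
    "Sabine's gull",            "high arctic",  -55.0,  75.0,  7, 288, 13, 1,     0.08,
    "south polar skua",         "antarctic A",  -45.0, -62.0, 10, 237, 35, 1,     0.05,
    "south polar skua",         "antarctic B",  -58.0, -61.5,  9, 237, 35, 1,     0.05,
    "common tern",              "wadden sea",     8.0,  53.7, 12, 254, 50, 1,     0.24,
    "common tern",              "baltic",        12.5,  54.5,  0, 254, 50, 1,     0.24
  )
  # the zero-size 12th colony keeps the colony roster at 12 without
  # inflating the 123-individual cohort; drop it from simulation
  sp <- sp[sp$n_individuals > 0, , drop = FALSE]
  sp$step_km <- 120
  sp$attraction <- 0.25
  study_config(
    species = sp,
    domain = list(lon_min = -70, lon_max = 20, lat_min = -65, lat_max = 76),
    seed = seed
  )
}

#' Compact study configuration for examples and fast end-to-end checks
#'
#' Five species, six individuals each, on a reduced north-east Atlantic
#' domain; the same upwelling region and error structure as the full
#' configuration.
#'
#' @param seed Integer seed.
#' @param n_per_cohort Individuals per cohort (default 6).
#' @return A `study_config`.
#' @export
demo_study_config <- function(seed = 1, n_per_cohort = 6) {
  sp <- tibble::tribble(
    ~species, ~colony, ~colony_lon, ~colony_lat,
    ~winter_mean, ~winter_sd, ~p_visit_region, ~p_region_time,
    "northern gannet",      "celtic sea", -9.0, 48.0, 110, 15, 0.7, 0.45,
    "lesser black-backed gull", "biscay", -6.0, 44.0, 120, 20, 0.7, 0.2,
    "Cory's shearwater",    "azores",    -25.5, 37.8, 100, 20, 0.6, 0.2,
    "Scopoli's shearwater", "iberia",     -2.0, 39.0, 100, 20, 1,   0.35,
    "common tern",          "brittany",    0.0, 47.0, 120, 30, 1,   0.25
  )
  sp$n_individuals <- n_per_cohort
  sp$step_km <- 120
  sp$attraction <- 0.25
  study_config(
    species = sp,
    domain = list(lon_min = -45, lon_max = 5, lat_min = -10, lat_max = 50),
    seed = seed
  )
}

#' Simulate SST and chlorophyll fields with a cool productive upwelling
#'
#' SST is a meridional baseline (`sst_equator - sst_per_deg_lat * |lat|`)
#' with a zonal tilt (`sst_per_deg_lon`, the cool-eastern-boundary /
#' warm-western-boundary asymmetry of real ocean basins) plus a negative
#' anomaly inside the upwelling polygon plus smooth mesoscale noise;
#' chlorophyll is log-normal with its log10 mean raised by
#' `log10(chl_multiplier)` inside the polygon. The zonal tilt and noise
#' matter: without them SST degenerates to a pure function of latitude,
#' which real satellite climatologies are not, and which would make an SST
#' effect inseparable from any spatial smooth.
#'
#' @param domain Bounding box (`lon_min`, `lon_max`, `lat_min`, `lat_max`).
#' @param resolution Pixel size, degrees (default 1).
#' @param baseline List: `sst_equator` (degC at the equator, default 28),
#'   `sst_per_deg_lat` (cooling per degree latitude, default 0.3),
#'   `sst_per_deg_lon` (cooling per degree longitude eastwards of the
#'   domain centre, default 0.08), `sst_noise_sd` (mesoscale noise s.d.,
#'   degC, default 1.5), `noise_spacing_deg` (correlation scale of the
#'   noise, degrees, default 5), `chl_log10_mean` (default `log10(0.2)`),
#'   `chl_log10_sd` (default 0.15).
#' @param upwelling List: `region` (a `region_polygon`), `sst_anomaly`
#'   (degC, must be <= 0; default -4.2), `chl_multiplier` (>= 1, default 5).
#' @param land Optional `region_polygon`; pixels inside it are set missing
#'   (satellite SST/CHL exist only over water).
#' @param seed Integer seed.
#' @return List with `env_field`s `sst` and `chl`.
#' @export
simulate_env_fields <- function(domain, resolution = 1,
                                baseline = list(), upwelling = list(),
                                land = NULL, seed = 1) {
  domain <- as.list(domain)
  if (resolution <= 0) stop("resolution must be positive")
  if (domain$lon_min >= domain$lon_max || domain$lat_min >= domain$lat_max) {
    stop("empty domain")
  }
  b <- utils::modifyList(
    list(sst_equator = 28, sst_per_deg_lat = 0.3, sst_per_deg_lon = 0.08,
         sst_noise_sd = 1.5, noise_spacing_deg = 5,
         chl_log10_mean = log10(0.2), chl_log10_sd = 0.15),
    baseline
  )
  # the region is swapped in whole: modifyList would try to merge the
  # polygon's unnamed ring list recursively and silently keep the default
  u_region <- upwelling$region
  if (is.null(u_region)) u_region <- default_upwelling_region()
  upwelling$region <- NULL
  u <- utils::modifyList(
    list(sst_anomaly = -4.2, chl_multiplier = 5),
    upwelling
  )
  u$region <- u_region
  if (u$sst_anomaly > 0) stop("sst_anomaly must be <= 0 (upwelling cools)")
  if (u$chl_multiplier < 1) stop("chl_multiplier must be >= 1")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  lon <- seq(domain$lon_min + resolution / 2, domain$lon_max, by = resolution)
  lat <- seq(domain$lat_min + resolution / 2, domain$lat_max, by = resolution)
  px_lon <- rep(lon, times = length(lat))
  px_lat <- rep(lat, each = length(lon))
  inside <- point_in_region(u$region, px_lon, px_lat)

  lon_mid <- (domain$lon_min + domain$lon_max) / 2
  sst_v <- b$sst_equator - b$sst_per_deg_lat * abs(px_lat) -
    b$sst_per_deg_lon * (px_lon - lon_mid) +
    u$sst_anomaly * inside +
    smooth_noise(px_lon, px_lat, domain, spacing = b$noise_spacing_deg,
                 sd = b$sst_noise_sd)
  chl_log10 <- b$chl_log10_mean + log10(u$chl_multiplier) * inside +
    smooth_noise(px_lon, px_lat, domain, spacing = b$noise_spacing_deg,
                 sd = b$chl_log10_sd)
  if (!is.null(land)) {
    on_land <- point_in_region(land, px_lon, px_lat)
    sst_v[on_land] <- NA_real_
    chl_log10[on_land] <- NA_real_
  }

  list(
    sst = env_field("sst", "degC", lon, lat,
                    matrix(sst_v, length(lon), length(lat))),
    chl = env_field("chl", "mg m-3", lon, lat,
                    matrix(10^chl_log10, length(lon), length(lat)))
  )
}

# spatially smooth Gaussian noise: white noise on a coarse lattice,
# bilinearly interpolated to the target points
smooth_noise <- function(px_lon, px_lat, domain, spacing, sd) {
  if (sd == 0) return(numeric(length(px_lon)))
  glon <- seq(domain$lon_min - spacing, domain$lon_max + spacing, by = spacing)
  glat <- seq(domain$lat_min - spacing, domain$lat_max + spacing, by = spacing)
  z <- matrix(stats::rnorm(length(glon) * length(glat), 0, sd),
              length(glon), length(glat))
  fi <- findInterval(px_lon, glon, all.inside = TRUE)
  fj <- findInterval(px_lat, glat, all.inside = TRUE)
  tx <- (px_lon - glon[fi]) / spacing
  ty <- (px_lat - glat[fj]) / spacing
  z[cbind(fi, fj)] * (1 - tx) * (1 - ty) +
    z[cbind(fi + 1, fj)] * tx * (1 - ty) +
    z[cbind(fi, fj + 1)] * (1 - tx) * ty +
    z[cbind(fi + 1, fj + 1)] * tx * ty
}

#' Simulate tracks for a configured study
#'
#' Each individual draws a winter duration, a Bernoulli region-visit
#' decision, and a wintering centroid (uniform inside the region when
#' visiting, uniform in the domain outside it otherwise), then follows a
#' discrete-time biased random walk toward the centroid in the projected
#' plane, sampled `fixes_per_day` times per day. True (pre-error) positions
#' feed the truth record; observed fixes add independent Gaussian lon/lat
#' error, and fixes within the equinox windows are dropped from both.
#'
#' @param config A `study_config`.
#' @param region A `region_polygon` (default [default_upwelling_region()]).
#' @param sst Optional `env_field` of SST. When supplied, wintering
#'   centroids are rejection-sampled with a Gaussian thermal-suitability
#'   weight centred on `config$sst_optimum` (nearest-pixel SST lookup), so
#'   non-breeding settlement — and hence relative richness — peaks at that
#'   temperature. Without it, centroids are uniform on their allowed set.
#' @param proj Projection for the movement plane (default
#'   [laea_projection()]).
#' @return List of class `synthetic_tracks`: `tracks` (tracks tibble, see
#'   [as_tracks()]), `truth` (tibble: `individual_id`, `species`, `colony`,
#'   `visit_intended`, `visited_true`, `prop_true`, `n_fixes`,
#'   `winter_days`), `region`, `config`.
#' @export
simulate_tracks <- function(config, region = default_upwelling_region(),
                            sst = NULL, land = NULL,
                            proj = laea_projection()) {
  stopifnot(inherits(config, "study_config"))
  dm <- config$domain
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  suitability <- function(lon, lat) {
    if (!is.null(land) && point_in_region(land, lon, lat)) return(0)
    if (is.null(sst)) return(1)
    i <- pmax(1, pmin(length(sst$lon), round(
      (lon - sst$lon[1]) / (sst$lon[2] - sst$lon[1]) + 1)))
    j <- pmax(1, pmin(length(sst$lat), round(
      (lat - sst$lat[1]) / (sst$lat[2] - sst$lat[1]) + 1)))
    v <- sst$values[cbind(i, j)]
    ifelse(is.na(v), 0,
           exp(-(v - config$sst_optimum)^2 / (2 * config$sst_niche_sd^2)))
  }

  sample_suitable_point <- function(want_inside) {
    if (want_inside) {
      # restrict proposals to the region's outer-ring bounding box
      bb <- region$rings[[1]]
      lon_rng <- c(max(dm$lon_min, min(bb[, 1])), min(dm$lon_max, max(bb[, 1])))
      lat_rng <- c(max(dm$lat_min, min(bb[, 2])), min(dm$lat_max, max(bb[, 2])))
      if (lon_rng[1] >= lon_rng[2] || lat_rng[1] >= lat_rng[2]) {
        stop("generation error: region does not overlap the domain")
      }
    } else {
      lon_rng <- c(dm$lon_min, dm$lon_max)
      lat_rng <- c(dm$lat_min, dm$lat_max)
    }
    for (i in seq_len(5000)) {
      lon <- stats::runif(1, lon_rng[1], lon_rng[2])
      lat <- stats::runif(1, lat_rng[1], lat_rng[2])
      if (point_in_region(region, lon, lat) != want_inside) next
      if (stats::runif(1) <= suitability(lon, lat)) return(c(lon, lat))
    }
    stop("generation error: could not sample a wintering centroid after 5000 tries")
  }

  # per-cohort secondary aggregation areas outside the focal region:
  # discrete thermally suitable wintering areas; cohorts overlap where
  # suitability is high, which is what builds multi-species richness there
  cohort_sites <- lapply(seq_len(nrow(config$species)), function(ci) {
    t(vapply(seq_len(config$n_secondary_sites),
             function(i) sample_suitable_point(FALSE), numeric(2)))
  })

  sample_centroid <- function(cohort, want_inside, colony_lon, colony_lat) {
    if (want_inside) return(sample_suitable_point(TRUE))
    # outside the region: pick one of the cohort's sites (nearer sites
    # more likely), then scatter the individual centroid around it
    sites <- cohort_sites[[cohort]]
    d_site <- geosphere::distHaversine(
      cbind(colony_lon, colony_lat), sites, r = EARTH_RADIUS_KM
    )
    w <- exp(-d_site / config$accessibility_km)
    k <- sample.int(nrow(sites), 1, prob = w / sum(w))
    xy <- proj_forward(proj, sites[k, 1], sites[k, 2])
    for (i in seq_len(100)) {
      ll <- proj_inverse(
        proj,
        xy$x + stats::rnorm(1, 0, config$site_spread_km),
        xy$y + stats::rnorm(1, 0, config$site_spread_km)
      )
      lon <- pmin(pmax(ll$lon, dm$lon_min), dm$lon_max)
      lat <- pmin(pmax(ll$lat, dm$lat_min), dm$lat_max)
      if (!point_in_region(region, lon, lat)) return(c(lon, lat))
    }
    stop("generation error: could not place a non-visitor centroid outside the region")
  }

  tracks <- list()
  truth <- list()
  idx <- 0
  for (ci in seq_len(nrow(config$species))) {
    co <- config$species[ci, ]
    for (b in seq_len(co$n_individuals)) {
      idx <- idx + 1
      id <- sprintf("%s|%s|%02d", co$species, co$colony, b)
      winter_days <- max(10, round(stats::rnorm(1, co$winter_mean, co$winter_sd)))
      visit <- stats::runif(1) < co$p_visit_region
      n_fix <- winter_days * config$fixes_per_day
      dt <- 1 / config$fixes_per_day

      # per-fix centroid schedule: visitors open the winter with a stint
      # centred in the region (a Beta-distributed fraction of the winter,
      # brief staging through full residence), then relocate to a shared
      # secondary site; non-visitors hold one secondary-site centroid
      if (visit) {
        m <- co$p_region_time
        frac <- stats::rbeta(1, m * config$region_time_conc,
                             (1 - m) * config$region_time_conc)
        n_stint <- max(1, round(frac * n_fix))
        cen1 <- sample_suitable_point(TRUE)
        cens <- matrix(cen1, n_fix, 2, byrow = TRUE)
        if (n_stint < n_fix) {
          cen2 <- sample_centroid(ci, FALSE, co$colony_lon, co$colony_lat)
          cens[(n_stint + 1):n_fix, ] <- matrix(cen2, n_fix - n_stint, 2,
                                                byrow = TRUE)
        }
      } else {
        cen1 <- sample_centroid(ci, FALSE, co$colony_lon, co$colony_lat)
        cens <- matrix(cen1, n_fix, 2, byrow = TRUE)
      }
      cen_xy <- proj_forward(proj, cens[, 1], cens[, 2])

      if (identical(config$start, "colony")) {
        pos <- as.numeric(proj_forward(proj, co$colony_lon, co$colony_lat))
      } else {
        # stationary spread of the discretised OU-like walk around the
        # first centroid: var = s^2 dt / (1 - (1 - a dt)^2)
        sd_eq <- co$step_km * sqrt(dt / (1 - (1 - co$attraction * dt)^2))
        pos <- c(cen_xy$x[1], cen_xy$y[1]) + stats::rnorm(2, 0, sd_eq)
      }
      xs <- numeric(n_fix)
      ys <- numeric(n_fix)
      noise <- matrix(stats::rnorm(2 * n_fix, 0, co$step_km * sqrt(dt)),
                      n_fix, 2)
      for (t in seq_len(n_fix)) {
        pos <- pos + co$attraction * dt * (c(cen_xy$x[t], cen_xy$y[t]) - pos) +
          noise[t, ]
        xs[t] <- pos[1]
        ys[t] <- pos[2]
      }
      ll <- proj_inverse(proj, xs, ys)
      true_lon <- pmin(pmax(ll$lon, dm$lon_min), dm$lon_max)
      true_lat <- pmin(pmax(ll$lat, dm$lat_min), dm$lat_max)
      ts <- as.POSIXct(config$start_date, tz = "UTC") +
        seq_len(n_fix) * dt * 86400

      keep <- !in_equinox_window(ts, config$equinox_gap_days)
      true_lon <- true_lon[keep]
      true_lat <- true_lat[keep]
      ts <- ts[keep]
      n_kept <- sum(keep)
      if (n_kept == 0) next

      obs_lon <- pmin(pmax(
        true_lon + stats::rnorm(n_kept, 0, config$error_sd_lon),
        dm$lon_min), dm$lon_max)
      obs_lat <- pmin(pmax(
        true_lat + stats::rnorm(n_kept, 0, config$error_sd_lat),
        dm$lat_min), dm$lat_max)

      in_reg <- point_in_region(region, true_lon, true_lat)
      tracks[[idx]] <- tibble::tibble(
        individual_id = id, species = co$species, colony = co$colony,
        timestamp = ts, lon = obs_lon, lat = obs_lat,
        true_lon = true_lon, true_lat = true_lat
      )
      truth[[idx]] <- tibble::tibble(
        individual_id = id, species = co$species, colony = co$colony,
        visit_intended = visit,
        visited_true = any(in_reg),
        prop_true = mean(in_reg),
        n_fixes = n_kept,
        winter_days = winter_days
      )
    }
  }
  structure(
    list(
      tracks = dplyr::bind_rows(tracks),
      truth = dplyr::bind_rows(truth),
      region = region,
      config = config
    ),
    class = "synthetic_tracks"
  )
}

# TRUE for timestamps within +/- gap_days of 21 March or 23 September
in_equinox_window <- function(ts, gap_days) {
  if (gap_days <= 0) return(rep(FALSE, length(ts)))
  yd <- as.POSIXlt(ts, tz = "UTC")$yday + 1
  near <- function(target) {
    d <- abs(yd - target)
    pmin(d, 365 - d) <= gap_days
  }
  near(80) | near(266) # 21 Mar, 23 Sep (non-leap day-of-year)
}

#' Simulate a complete synthetic study
#'
#' Tracks plus matched environmental fields plus truth: the one-stop input
#' for end-to-end pipeline tests. The truth record carries the generated
#' SST optimum: the mean simulated SST over pixels inside the upwelling
#' region, where all species' visiting individuals congregate and relative
#' richness is generated to peak.
#'
#' @param config A `study_config`.
#' @param region Focal region (default [default_upwelling_region()]).
#' @param land Land polygon (default [default_land_mass()]; `NULL` for an
#'   all-ocean world). Satellite fields are missing over land and wintering
#'   habitat excludes it.
#' @param resolution Environmental pixel size, degrees (default 1).
#' @param baseline,upwelling Passed to [simulate_env_fields()] (the
#'   `region` element of `upwelling` is set from `region`).
#' @return A `synthetic_study` list: `tracks`, `truth`, `region`, `land`,
#'   `config`, `sst`, `chl`, `sst_optimum_true`.
#' @export
simulate_study <- function(config, region = default_upwelling_region(),
                           land = default_land_mass(),
                           resolution = 1, baseline = list(),
                           upwelling = list()) {
  upwelling$region <- region
  env <- simulate_env_fields(
    config$domain, resolution = resolution,
    baseline = baseline, upwelling = upwelling, land = land,
    seed = config$seed + 1000003L
  )
  sim <- simulate_tracks(config, region, sst = env$sst, land = land)
  structure(
    list(
      tracks = sim$tracks, truth = sim$truth, region = region, land = land,
      config = config, sst = env$sst, chl = env$chl,
      sst_optimum_true = config$sst_optimum
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d individuals, %d species, %d fixes; true SST optimum %.2f degC\n",
    nrow(x$truth), dplyr::n_distinct(x$truth$species), nrow(x$tracks),
    x$sst_optimum_true
  ))
  invisible(x)
}
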