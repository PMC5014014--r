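# Gridded environmental fields (SST, chlorophyll) on regular lon/lat axes,
# seasonal climatology composites, and per-hexagon covariate extraction.

#' Create a gridded environmental field
#'
#' @param var Variable name (e.g. `"sst"`, `"chl"`).
#' @param units Unit string (e.g. `"degC"`, `"mg m-3"`).
#' @param lon,lat Strictly increasing axis vectors (pixel centres, degrees).
#' @param values Matrix `length(lon)` x `length(lat)`; `NA` marks missing.
#' @param month,year Optional integers identifying a monthly slice.
#' @return An `env_field` object.
#' @export
env_field <- function(var, units, lon, lat, values, month = NULL, year = NULL) {
  stopifnot(
    is.numeric(lon), is.numeric(lat),
    all(diff(lon) > 0), all(diff(lat) > 0),
    is.matrix(values),
    nrow(values) == length(lon), ncol(values) == length(lat)
  )
  structure(
    list(var = var, units = units, lon = lon, lat = lat, values = values,
         month = month, year = year),
    class = "env_field"
  )
}

#' @export
print.env_field <- function(x, ...) {
  cat(sprintf(
    "env_field '%s' [%s]: %d x %d pixels, lon [%g, %g], lat [%g, %g]%s\n",
    x$var, x$units, length(x$lon), length(x$lat),
    min(x$lon), max(x$lon), min(x$lat), max(x$lat),
    if (!is.null(x$month)) sprintf(", %04d-%02d", x$year, x$month) else ""
  ))
  invisible(x)
}

#' Convert an env_field to a long tibble of pixel centres
#'
#' @param field An `env_field`.
#' @return Tibble: `lon`, `lat`, `value`.
#' @export
env_field_tbl <- function(field) {
  stopifnot(inherits(field, "env_field"))
  tibble::tibble(
    lon = rep(field$lon, times = length(field$lat)),
    lat = rep(field$lat, each = length(field$lon)),
    value = as.vector(field$values)
  )
}

#' Seasonal climatology composite of monthly fields
#'
#' Per-pixel unweighted mean over the selected month-by-year slices, ignoring
#' missing pixels; a pixel missing in every slice stays missing. When the
#' month window spans the year boundary (contains both December and January,
#' as in a December-March boreal winter), a slice's season is attributed to
#' the year its December falls in, so `years = 2002:2010` pools
#' Dec 2002 - Mar 2003 through Dec 2010 - Mar 2011.
#'
#' @param fields List of `env_field` monthly slices (same grid, with `month`
#'   and `year` set).
#' @param months Integer months to include (default `c(12, 1, 2, 3)`).
#' @param years Integer season years to include.
#' @return A composite `env_field`.
#' @export
seasonal_climatology <- function(fields, months = c(12, 1, 2, 3), years) {
  stopifnot(length(fields) >= 1)
  ref <- fields[[1]]
  spans_boundary <- all(c(12, 1) %in% months)
  keep <- vapply(fields, function(f) {
    stopifnot(inherits(f, "env_field"))
    if (is.null(f$month) || is.null(f$year)) {
      stop("each slice needs month and year metadata")
    }
    if (!identical(f$lon, ref$lon) || !identical(f$lat, ref$lat)) {
      stop("all slices must share one grid")
    }
    season_year <- if (spans_boundary && f$month < 6) f$year - 1 else f$year
    (f$month %in% months) && (season_year %in% years)
  }, logical(1))
  if (!any(keep)) stop("no slices match the requested months/years")
  slices <- fields[keep]
  arr <- vapply(slices, function(f) f$values,
                matrix(0, length(ref$lon), length(ref$lat)))
  dim(arr) <- c(length(ref$lon), length(ref$lat), length(slices))
  n_ok <- apply(!is.na(arr), c(1, 2), sum)
  mean_v <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  mean_v[n_ok == 0] <- NA_real_
  env_field(ref$var, ref$units, ref$lon, ref$lat, mean_v)
}

#' Per-hexagon environmental covariates
#'
#' Averages raster pixels whose centres fall inside each hexagon (no area
#' weighting; adequate when pixels are much smaller than cells). Chlorophyll
#' is averaged in natural units over the cell and then log10-transformed.
#' Ocean cells with no valid pixel for either variable are dropped, with the
#' count recorded in the `n_dropped` attribute.
#'
#' @param grid A `hex_grid`.
#' @param sst `env_field` of sea-surface temperature (degC).
#' @param chl `env_field` of chlorophyll a (mg m-3).
#' @param null_surface Optional [accessibility_surface()] result to join.
#' @return Tibble: `cell`, `x`, `y` (projected km), `sst_mean`, `chl_log10`,
#'   and `null_usage` when supplied; ocean cells only, no missing values.
#' @export
cell_covariates <- function(grid, sst, chl, null_surface = NULL) {
  stopifnot(inherits(grid, "hex_grid"))
  agg <- function(field, fun) {
    px <- env_field_tbl(field)
    px$cell <- locate_points(grid, px$lon, px$lat)
    px <- px[!is.na(px$cell) & !is.na(px$value), , drop = FALSE]
    dplyr::summarise(
      dplyr::group_by(px, .data$cell),
      value = fun(.data$value),
      .groups = "drop"
    )
  }
  sst_c <- agg(sst, mean)
  chl_c <- agg(chl, mean)
  chl_c$value <- ifelse(chl_c$value > 0, log10(chl_c$value), NA_real_)

  out <- grid$cells[grid$cells$ocean, c("cell", "x", "y")]
  out$sst_mean <- sst_c$value[match(out$cell, sst_c$cell)]
  out$chl_log10 <- chl_c$value[match(out$cell, chl_c$cell)]
  if (!is.null(null_surface)) {
    out$null_usage <- null_surface$null_usage[match(out$cell, null_surface$cell)]
  }
  complete <- stats::complete.cases(out)
  n_dropped <- sum(!complete)
  out <- out[complete, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write/read an env_field as CF-style netCDF
#'
#' Single-variable netCDF with `lon`/`lat` dimensions (degrees_east /
#' degrees_north), an `NaN`-free fill value, and optional `month`/`year`
#' global attributes for monthly slices.
#'
#' @param field An `env_field`.
#' @param path File path.
#' @return `read_env_nc()` returns an `env_field`.
#' @export
write_env_nc <- function(field, path) {
  stopifnot(inherits(field, "env_field"))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  fill <- -9.96921e36
  var <- ncdf4::ncvar_def(field$var, field$units, list(dim_lon, dim_lat),
                          missval = fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(var))
  on.exit(ncdf4::nc_close(nc))
  vals <- field$values
  vals[is.na(vals)] <- fill
  ncdf4::ncvar_put(nc, var, vals)
  if (!is.null(field$month)) {
    ncdf4::ncatt_put(nc, 0, "slice_month", as.integer(field$month))
    ncdf4::ncatt_put(nc, 0, "slice_year", as.integer(field$year))
  }
  invisible(path)
}

#' @rdname write_env_nc
#' @export
read_env_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  var <- nc$var[[1]]
  vals <- ncdf4::ncvar_get(nc, var, collapse_degen = FALSE)
  dim(vals) <- c(var$dim[[1]]$len, var$dim[[2]]$len)
  m <- ncdf4::ncatt_get(nc, 0, "slice_month")
  y <- ncdf4::ncatt_get(nc, 0, "slice_year")
  env_field(
    var$name, var$units,
    lon = as.numeric(var$dim[[1]]$vals), lat = as.numeric(var$dim[[2]]$vals),
    values = vals,
    month = if (m$hasatt) m$value else NULL,
    year = if (y$hasatt) y$value else NULL
  )
}
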