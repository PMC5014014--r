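# Null usage: the expected per-cell usage under habitat availability and
# sampling effort alone. Availability is the ocean mask; effort enters as
# per-colony tracked-sample-size weights on an exponential-decay
# accessibility kernel in great-circle distance. This is a transparent
# stand-in with the two stated ingredients (availability + effort); the
# kernel family and range scale are deliberately exposed because the
# formulation is the least constrained part of the analysis.

#' Colony accessibility null-usage surface
#'
#' For each ocean cell, `sum over colonies of n_tracked *
#' exp(-d(colony, cell centre) / range_scale_km)` with `d` the great-circle
#' distance, normalised to sum to 1 over ocean cells. Land cells get 0.
#'
#' @param grid A `hex_grid` (its `ocean` flag defines availability).
#' @param colonies Data frame with columns `lon`, `lat`, `n_tracked`,
#'   `range_scale_km` (one row per colony).
#' @return Tibble of ocean cells: `cell`, `x`, `y`, `null_usage`, with the
#'   colony table attached as attribute `colonies`. Class
#'   `null_usage_surface`.
#' @examples
#' g <- build_hex_grid(list(lon_min = -20, lon_max = -10,
#'                          lat_min = 10, lat_max = 20))
#' s <- accessibility_surface(
#'   g, data.frame(lon = -15, lat = 15, n_tracked = 10, range_scale_km = 500)
#' )
#' sum(s$null_usage) # 1
#' @export
accessibility_surface <- function(grid, colonies) {
  stopifnot(inherits(grid, "hex_grid"))
  req <- c("lon", "lat", "n_tracked", "range_scale_km")
  if (!all(req %in% names(colonies))) {
    stop("colonies needs columns: ", paste(req, collapse = ", "))
  }
  if (any(colonies$n_tracked < 1)) stop("n_tracked must be >= 1")
  if (any(colonies$range_scale_km <= 0)) stop("range_scale_km must be positive")
  cells <- grid$cells[grid$cells$ocean, , drop = FALSE]
  if (nrow(cells) == 0) stop("degenerate surface: no ocean cells in grid")

  usage <- numeric(nrow(cells))
  for (i in seq_len(nrow(colonies))) {
    d_km <- geosphere::distHaversine(
      cbind(colonies$lon[i], colonies$lat[i]),
      cbind(cells$lon, cells$lat),
      r = EARTH_RADIUS_KM
    )
    usage <- usage + colonies$n_tracked[i] * exp(-d_km / colonies$range_scale_km[i])
  }
  out <- tibble::tibble(
    cell = cells$cell, x = cells$x, y = cells$y,
    null_usage = usage / sum(usage)
  )
  attr(out, "colonies") <- tibble::as_tibble(colonies)
  class(out) <- c("null_usage_surface", class(out))
  out
}
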