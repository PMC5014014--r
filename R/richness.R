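# Binned occupancy and the relative species-richness surface. "Relative"
# because richness counts only the tracked study species: the number of
# species with at least one location in each hexagon over the study window
# (optionally restricted to a month window for season-resolved surfaces).

#' Bin fixes into grid cells, by species
#'
#' Each fix increments its cell's per-species fix count; fixes outside the
#' tiled domain are excluded and counted in the `n_out_of_domain` attribute.
#'
#' @param tracks A tracks table (see [as_tracks()]).
#' @param grid A `hex_grid`.
#' @param months Optional integer vector of calendar months (1-12); only
#'   fixes in these months are binned. Default: all.
#' @return Tibble: `cell`, `species`, `n_fixes`, `n_individuals`, with
#'   attribute `n_out_of_domain`.
#' @export
occupancy <- function(tracks, grid, months = NULL) {
  stopifnot(inherits(grid, "hex_grid"))
  if (nrow(tracks) == 0) {
    out <- tibble::tibble(
      cell = integer(0), species = character(0),
      n_fixes = integer(0), n_individuals = integer(0)
    )
    attr(out, "n_out_of_domain") <- 0L
    return(out)
  }
  tracks <- as_tracks(tracks)
  if (!is.null(months)) {
    m <- as.integer(format(tracks$timestamp, "%m"))
    tracks <- tracks[m %in% months, , drop = FALSE]
  }
  if (nrow(tracks) == 0) {
    out <- tibble::tibble(
      cell = integer(0), species = character(0),
      n_fixes = integer(0), n_individuals = integer(0)
    )
    attr(out, "n_out_of_domain") <- 0L
    return(out)
  }
  tracks$cell <- locate_points(grid, tracks$lon, tracks$lat)
  n_out <- sum(is.na(tracks$cell))
  tracks <- tracks[!is.na(tracks$cell), , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(tracks, .data$cell, .data$species),
    n_fixes = dplyr::n(),
    n_individuals = dplyr::n_distinct(.data$individual_id),
    .groups = "drop"
  )
  attr(out, "n_out_of_domain") <- n_out
  out
}

#' Relative species richness per cell
#'
#' Number of study species "occurring" in each cell, i.e. with at least
#' `min_fixes` binned fixes there. Cells with no occupancy get richness 0,
#' so the surface is defined over the whole grid.
#'
#' @param occ An [occupancy()] table.
#' @param grid A `hex_grid` (supplies the full cell set).
#' @param min_fixes Minimum per-species fix count for the species to count
#'   as occurring in a cell (denoising threshold, default 1).
#' @return Tibble: `cell`, `x`, `y`, `lon`, `lat`, `ocean`, `richness`.
#' @export
relative_richness <- function(occ, grid, min_fixes = 1) {
  stopifnot(inherits(grid, "hex_grid"))
  occ <- occ[occ$n_fixes >= min_fixes, , drop = FALSE]
  rich <- dplyr::summarise(
    dplyr::group_by(occ, .data$cell),
    richness = dplyr::n_distinct(.data$species),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid$cells, rich, by = "cell")
  out$richness <- as.integer(ifelse(is.na(out$richness), 0L, out$richness))
  out <- dplyr::select(
    out, "cell", "x", "y", "lon", "lat", "ocean", "richness"
  )
  class(out) <- c("richness_surface", class(out))
  out
}

#' Export a richness surface as GeoJSON cell polygons
#'
#' @param surface A [relative_richness()] result.
#' @param grid The `hex_grid` the surface was computed on.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_richness_geojson <- function(surface, grid, path) {
  verts <- hex_vertices(grid, surface$cell)
  feats <- lapply(seq_len(nrow(surface)), function(i) {
    vv <- verts[verts$cell == surface$cell[i], , drop = FALSE]
    ring <- lapply(c(seq_len(6), 1), function(k) c(vv$lon[k], vv$lat[k]))
    list(
      type = "Feature",
      properties = list(
        cell = surface$cell[i],
        x = surface$x[i], y = surface$y[i],
        ocean = surface$ocean[i],
        richness = surface$richness[i]
      ),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
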