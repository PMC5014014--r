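# Region-overlap statistics: per-fix membership, per-individual proportions,
# per-species summaries and the cross-species aggregate. "Proportion of time"
# is computed as the proportion of fixes, appropriate for an equal-cadence
# (twice-daily) light-logger fix regime.

#' Validate a tracks table
#'
#' A tracks table holds one row per location fix with columns
#' `individual_id`, `species`, `colony`, `timestamp` (POSIXct, UTC),
#' `lon`, `lat`. Fixes are returned sorted by individual and time.
#'
#' @param tracks A data frame of fixes.
#' @return The validated tibble (sorted).
#' @export
as_tracks <- function(tracks) {
  req <- c("individual_id", "species", "colony", "timestamp", "lon", "lat")
  missing_cols <- setdiff(req, names(tracks))
  if (length(missing_cols) > 0) {
    stop("tracks table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tracks <- tibble::as_tibble(tracks)
  if (nrow(tracks) == 0) stop("tracks table has no fixes")
  if (any(!is.finite(tracks$lon)) || any(!is.finite(tracks$lat))) {
    stop("non-finite coordinates in tracks table")
  }
  bad_lat <- which(tracks$lat < -90 | tracks$lat > 90)
  if (length(bad_lat) > 0) {
    stop("latitude out of [-90, 90] at row(s): ",
         paste(utils::head(bad_lat, 5), collapse = ", "))
  }
  tracks$lon <- normalize_lon(tracks$lon)
  tracks <- dplyr::arrange(tracks, .data$individual_id, .data$timestamp)
  dup <- duplicated(tracks[, c("individual_id", "timestamp")])
  if (any(dup)) {
    stop("duplicate (individual, timestamp) fix at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  tracks
}

#' Per-individual proportion of fixes inside a region
#'
#' For each individual, the number of fixes inside the region divided by its
#' total number of fixes, each fix equally weighted.
#'
#' @param tracks A tracks table (see [as_tracks()]).
#' @param region A `region_polygon`.
#' @return Tibble: `individual_id`, `species`, `colony`, `n_fixes`,
#'   `n_in_region`, `proportion`, `winter_days` (span between first and last
#'   fix, days).
#' @export
proportion_in_region <- function(tracks, region) {
  tracks <- as_tracks(tracks)
  tracks$in_region <- point_in_region(region, tracks$lon, tracks$lat)
  dplyr::summarise(
    dplyr::group_by(tracks, .data$individual_id, .data$species, .data$colony),
    n_fixes = dplyr::n(),
    n_in_region = sum(.data$in_region),
    proportion = .data$n_in_region / .data$n_fixes,
    winter_days = as.numeric(difftime(max(.data$timestamp),
                                      min(.data$timestamp), units = "days")),
    .groups = "drop"
  )
}

#' Species-level summary of region use
#'
#' One row per species: number of individuals, percentage with at least
#' `min_fixes_visit` fixes inside the region, and mean +/- sample s.d.
#' (n - 1 denominator) of winter period length, fix counts, in-region fix
#' counts and in-region proportions. For a species with a single individual
#' the s.d. is undefined and reported as 0 with `sd_defined = FALSE`.
#'
#' @param tracks A tracks table.
#' @param region A `region_polygon`.
#' @param min_fixes_visit Minimum in-region fixes to count an individual as
#'   visiting (default 1).
#' @return Tibble with columns `species`, `n`, `pct_visiting`,
#'   `winter_days_mean`, `winter_days_sd`, `n_locations_mean`,
#'   `n_locations_sd`, `in_region_mean`, `in_region_sd`, `proportion_mean`,
#'   `proportion_sd`, `sd_defined`.
#' @export
species_table <- function(tracks, region, min_fixes_visit = 1) {
  ind <- proportion_in_region(tracks, region)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- dplyr::summarise(
    dplyr::group_by(ind, .data$species),
    n = dplyr::n(),
    pct_visiting = 100 * mean(.data$n_in_region >= min_fixes_visit),
    winter_days_mean = mean(.data$winter_days),
    winter_days_sd = sd0(.data$winter_days),
    n_locations_mean = mean(.data$n_fixes),
    n_locations_sd = sd0(.data$n_fixes),
    in_region_mean = mean(.data$n_in_region),
    in_region_sd = sd0(.data$n_in_region),
    proportion_mean = mean(.data$proportion),
    proportion_sd = sd0(.data$proportion),
    sd_defined = dplyr::n() >= 2,
    .groups = "drop"
  )
  dplyr::arrange(out, .data$species)
}

#' Cross-species aggregate of visiting percentages
#'
#' Unweighted mean and sample standard deviation (n - 1 denominator) of the
#' species-level "% visiting" values, the headline statistic for how widely
#' an upwelling region is shared across tracked species.
#'
#' @param x A [species_table()] result (uses its `pct_visiting` column) or a
#'   numeric vector of species-level percentages.
#' @return Tibble: `n_species`, `mean_pct_visiting`, `sd_pct_visiting`.
#' @examples
#' cross_species_stats(c(71.4, 58.8, 25, 57.9, 100, 100, 100, 100))
#' @export
cross_species_stats <- function(x) {
  if (is.data.frame(x)) {
    if (!"pct_visiting" %in% names(x)) {
      stop("expected a species table with a pct_visiting column")
    }
    x <- x$pct_visiting
  }
  if (!is.numeric(x) || length(x) < 1) stop("need at least one percentage")
  tibble::tibble(
    n_species = length(x),
    mean_pct_visiting = mean(x),
    sd_pct_visiting = if (length(x) >= 2) stats::sd(x) else NA_real_
  )
}
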