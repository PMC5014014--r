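# Track CSV I/O. One row per fix:
# individual_id,species,colony,timestamp,lon,lat with ISO-8601 UTC
# timestamps, WGS84 lon/lat, lon normalised to [-180, 180).

#' Read a tracks CSV
#'
#' Expects a header `individual_id,species,colony,timestamp,lon,lat`;
#' timestamps ISO-8601 (UTC assumed when no zone is given). Fixes are
#' grouped by individual and sorted by time; duplicate (individual,
#' timestamp) rows, out-of-range coordinates and unparseable timestamps are
#' rejected with the offending row number.
#'
#' @param path CSV file path.
#' @return A tracks tibble (see [as_tracks()]).
#' @export
parse_tracks <- function(path) {
  # validation (missing columns, bad rows) is done explicitly below, so
  # readr's own column-mismatch warnings are redundant
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      individual_id = readr::col_character(),
      species = readr::col_character(),
      colony = readr::col_character(),
      timestamp = readr::col_character(),
      lon = readr::col_double(),
      lat = readr::col_double()
    )
  ))
  req <- c("individual_id", "species", "colony", "timestamp", "lon", "lat")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("tracks CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  fmts <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01",
                   tz = "UTC")
  for (f in fmts) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(raw$timestamp[todo], format = f,
                                    tz = "UTC"))
  }
  bad_ts <- which(is.na(ts) & !is.na(raw$timestamp))
  if (length(bad_ts) > 0) {
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(bad_ts, 5), collapse = ", "))
  }
  bad_lat <- which(raw$lat < -90 | raw$lat > 90)
  if (length(bad_lat) > 0) {
    stop("latitude out of [-90, 90] at row(s): ",
         paste(utils::head(bad_lat, 5), collapse = ", "))
  }
  bad_lon <- which(raw$lon < -360 | raw$lon > 360)
  if (length(bad_lon) > 0) {
    stop("longitude out of range at row(s): ",
         paste(utils::head(bad_lon, 5), collapse = ", "))
  }
  raw$timestamp <- ts
  as_tracks(raw)
}

#' Write a tracks table as CSV
#'
#' @param tracks A tracks tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  tracks <- as_tracks(tracks)
  out <- tracks[, c("individual_id", "species", "colony", "timestamp",
                    "lon", "lat")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Published multi-colony tracking summary table
#'
#' Species-level summary statistics (cohort sizes, percentage of individuals
#' visiting the Canary Current upwelling, winter-period lengths, location
#' counts) from a published pan-Atlantic eight-species geolocator study;
#' shipped as a plain-text fixture and used to parametrise
#' [default_study_config()] and as the input to the cross-species aggregate
#' (the winter-period s.d. is unavailable for one species and stored as NA).
#'
#' @return A tibble, one row per species.
#' @examples
#' cross_species_stats(atlantic_tracking_summary())
#' @export
atlantic_tracking_summary <- function() {
  path <- system.file("extdata", "atlantic_tracking_summary.csv",
                      package = "hexrich", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(),
    .default = readr::col_double()
  ))
}
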