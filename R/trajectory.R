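#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km. Spherical rather than
#' ellipsoidal geometry: the error (< 0.5%) is negligible next to every
#' other uncertainty in track-based distance estimation.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees; latitudes in [-90, 90],
#'   longitudes in [-180, 180]. Vectorized with the usual recycling.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 90, 0)  # quarter meridian, ~10007.5 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * .units$earth_radius_km * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(abs(lat) > 90)) {
    stop("latitude out of [-90, 90]", call. = FALSE)
  }
  if (any(!is.finite(lon)) || any(abs(lon) > 180)) {
    stop("longitude out of [-180, 180]", call. = FALSE)
  }
  invisible(NULL)
}

#' Construct a track of GPS fixes
#'
#' @param individual_id single string.
#' @param timestamp POSIXct vector, strictly increasing.
#' @param lat,lon decimal degrees.
#' @param species optional species label.
#' @param body_mass_kg optional body mass.
#' @return A tibble of class `track`, ordered in time.
#' @export
track <- function(individual_id, timestamp, lat, lon,
                  species = NA_character_, body_mass_kg = NA_real_) {
  stopifnot(inherits(timestamp, "POSIXct"))
  check_coords(lat, lon)
  ord <- order(timestamp)
  timestamp <- timestamp[ord]; lat <- lat[ord]; lon <- lon[ord]
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop("track timestamps must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(individual_id = individual_id, timestamp = timestamp,
                        lat = lat, lon = lon)
  attr(out, "species") <- species
  attr(out, "body_mass_kg") <- body_mass_kg
  class(out) <- c("track", class(out))
  out
}

#' Read Movebank-export-style tracking CSVs
#'
#' Expects columns for individual id, ISO 8601 timestamp, decimal latitude
#' and longitude (Movebank export naming `individual-local-identifier`,
#' `timestamp`, `location-lat`, `location-long` accepted, as are the plain
#' names used elsewhere in this package).
#'
#' @param path CSV file path.
#' @param sep field delimiter (default comma).
#' @return A list of `track` objects, one per individual.
#' @export
read_tracks_csv <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(cands) {
    hit <- intersect(cands, names(raw))
    if (!length(hit)) stop("tracking file lacks column: one of ",
                           paste(cands, collapse = "/"), call. = FALSE)
    raw[[hit[1]]]
  }
  id <- pick(c("individual_id", "individual-local-identifier"))
  ts <- parse_utc(pick(c("timestamp")))
  lat <- as.numeric(pick(c("lat", "location-lat")))
  lon <- as.numeric(pick(c("lon", "location-long")))
  df <- tibble::tibble(individual_id = as.character(id), timestamp = ts,
                       lat = lat, lon = lon)
  lapply(split(df, df$individual_id), function(d) {
    track(d$individual_id[1], d$timestamp, d$lat, d$lon)
  })
}

# Parse ISO-ish UTC timestamps element-wise. as.POSIXct picks its format
# from the first element, which silently drops the time of day for every
# fix when a midnight fix (printed date-only) happens to come first.
parse_utc <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  x[nchar(x) == 10] <- paste(x[nchar(x) == 10], "00:00:00")
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  if (any(is.na(out) & !is.na(x))) {
    stop("unparseable timestamp(s), expected ISO 8601: ",
         paste(utils::head(x[is.na(out)], 3), collapse = ", "), call. = FALSE)
  }
  out
}

# split fix indices into segments whose internal gaps are all <= max_gap_s
segment_indices <- function(ts, max_gap_s) {
  gaps <- diff(as.numeric(ts))
  split(seq_along(ts), cumsum(c(0, gaps > max_gap_s)))
}

#' Resample a track onto a uniform time grid
#'
#' Linear interpolation of latitude and longitude onto a grid with the
#' given spacing. Fix pairs separated by more than `max_gap_s` are never
#' bridged: the track is cut into segments there and each segment is
#' resampled independently, so gaps reduce coverage instead of fabricating
#' movement.
#'
#' @param trk a `track`.
#' @param interval_s grid spacing in seconds (> 0; default 3600, 1 h).
#' @param max_gap_s maximum inter-fix gap to interpolate across, seconds
#'   (default 7 days).
#' @return A `track` on the uniform grid with a `segment` column; a track
#'   with fewer than 2 fixes yields an empty track with a warning.
#' @export
regularize <- function(trk, interval_s = 3600, max_gap_s = 7 * 86400) {
  stopifnot(interval_s > 0, max_gap_s >= interval_s)
  if (nrow(trk) < 2) {
    warning("track has fewer than 2 fixes; nothing to regularize", call. = FALSE)
    out <- trk[0, ]
    out$segment <- integer(0)
    return(out)
  }
  segs <- segment_indices(trk$timestamp, max_gap_s)
  pieces <- lapply(seq_along(segs), function(k) {
    idx <- segs[[k]]
    if (length(idx) < 2) return(NULL)
    t0 <- as.numeric(trk$timestamp[idx])
    grid <- seq(t0[1], t0[length(t0)], by = interval_s)
    tibble::tibble(
      individual_id = trk$individual_id[1],
      timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
      lat = stats::approx(t0, trk$lat[idx], xout = grid)$y,
      lon = stats::approx(t0, trk$lon[idx], xout = grid)$y,
      segment = k)
  })
  out <- dplyr::bind_rows(pieces)
  attr(out, "species") <- attr(trk, "species")
  class(out) <- c("track", class(out))
  out
}

#' Path length and coverage of a track
#'
#' Sums consecutive great-circle distances, skipping any fix pair whose
#' time gap exceeds `max_gap_s` (movement across a data gap is unknown and
#' is never fabricated). Covered time is the spanned period minus the
#' excluded gaps; annualization scales the path linearly to 365 days of
#' covered time.
#'
#' @param trk a `track` with at least 2 fixes.
#' @param max_gap_s maximum bridgeable gap, seconds (default 7 d).
#' @param min_coverage summaries whose `coverage_fraction` falls below this
#'   are flagged unusable (default 0.5).
#' @return A one-row tibble: `individual_id`, `path_km`, `covered_days`,
#'   `spanned_days`, `coverage_fraction`, `annual_distance_km`, `usable`.
#' @export
path_length <- function(trk, max_gap_s = 7 * 86400, min_coverage = 0.5) {
  if (nrow(trk) < 2) stop("track needs at least 2 fixes", call. = FALSE)
  ts <- as.numeric(trk$timestamp)
  gaps <- diff(ts)
  ok <- gaps <= max_gap_s
  step_km <- haversine_km(trk$lat[-nrow(trk)], trk$lon[-nrow(trk)],
                          trk$lat[-1], trk$lon[-1])
  path_km <- sum(step_km[ok])
  covered_s <- sum(gaps[ok])
  spanned_s <- ts[length(ts)] - ts[1]
  covered_days <- covered_s / 86400
  coverage <- if (spanned_s > 0) covered_s / spanned_s else 0
  annual <- if (covered_days > 0) path_km * .units$days_per_year / covered_days else NA_real_
  tibble::tibble(
    individual_id = trk$individual_id[1],
    path_km = path_km,
    covered_days = covered_days,
    spanned_days = spanned_s / 86400,
    coverage_fraction = coverage,
    annual_distance_km = annual,
    usable = coverage >= min_coverage & covered_days > 0)
}

#' Species-level annual distance from individual tracks
#'
#' Mean of the per-individual annualized path lengths, with a
#' nonparametric bootstrap over individuals for the 95% percentile
#' interval. Unusable tracks (coverage below threshold) are excluded.
#'
#' @param tracks list of `track` objects.
#' @param max_gap_s,min_coverage passed to [path_length()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed; same seed, same interval, bit for bit.
#' @return An `uncertain_value` in km yr^-1 (basis `ci95`), with the
#'   per-individual summary table attached as attribute `"summaries"`.
#' @export
species_annual_distance <- function(tracks, max_gap_s = 7 * 86400,
                                    min_coverage = 0.5, n_boot = 1000,
                                    seed = 1L) {
  summaries <- dplyr::bind_rows(lapply(tracks, path_length,
                                       max_gap_s = max_gap_s,
                                       min_coverage = min_coverage))
  if (nrow(summaries) == 0) stop("no usable tracks", call. = FALSE)
  usable <- summaries$annual_distance_km[summaries$usable]
  if (length(usable) == 0) stop("no usable tracks", call. = FALSE)
  m <- mean(usable)
  if (length(usable) == 1) {
    out <- uncertain(m, m, m, basis = "ci95")
  } else {
    set.seed(seed)
    boot_means <- vapply(seq_len(n_boot), function(i)
      mean(sample(usable, replace = TRUE)), numeric(1))
    qs <- stats::quantile(boot_means, c(0.025, 0.975), names = FALSE, type = 7)
    out <- uncertain(m, min(qs[1], m), max(qs[2], m), basis = "ci95")
  }
  attr(out, "summaries") <- summaries
  out
}
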