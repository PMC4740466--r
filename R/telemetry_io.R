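#' Column-name schema for detection files
#'
#' Detection exports from receiver-download software vary only in column
#' names. The default schema matches the common vendor export (one header
#' row, UTC timestamps); pass different names to adapt to any CSV layout.
#'
#' @param timestamp,receiver,transmitter,depth column names in the file.
#'   `depth` may be `NA` if the file has no sensor column.
#' @return A named list usable as the `schema` argument of
#'   [read_detections()].
#' @export
detection_schema <- function(timestamp = "Date and Time (UTC)",
                             receiver = "Receiver",
                             transmitter = "Transmitter",
                             depth = "Sensor.Value") {
  list(timestamp = timestamp, receiver = receiver,
       transmitter = transmitter, depth = depth)
}

#' Read and normalise a detection CSV
#'
#' Reads raw detections (one row per decoded transmission), parses UTC
#' timestamps, drops malformed rows (counting them), collapses exact
#' duplicates (same timestamp, receiver and transmitter; first occurrence
#' kept — receiver-download overlaps produce exact duplicates) and returns
#' records sorted by time.
#'
#' @param path CSV file path.
#' @param schema column mapping from [detection_schema()].
#' @param max_malformed_frac abort if more than this fraction of rows fail
#'   to parse (default 1\%); below the threshold malformed rows are dropped
#'   with a warning.
#' @param depth_max_m transmitter depth rating in metres; sensor values
#'   outside \[0, `depth_max_m`\] are treated as sensor glitches and set
#'   to `NA`. Default 68 m, the rating of the depth transmitters used in
#'   the study design this package targets.
#' @return A tibble with columns `timestamp` (POSIXct UTC), `receiver_id`,
#'   `transmitter_id`, `depth_m`; attribute `n_malformed` counts dropped
#'   rows.
#' @export
read_detections <- function(path, schema = detection_schema(),
                            max_malformed_frac = 0.01, depth_max_m = 68) {
  if (!file.exists(path)) abort(sprintf("detection file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("timestamp", "receiver", "transmitter")
  for (field in needed) {
    if (!schema[[field]] %in% names(raw)) {
      abort(sprintf("schema error: column '%s' (%s) missing from %s",
                    schema[[field]], field, path))
    }
  }
  ts <- parse_utc(raw[[schema$timestamp]])
  depth <- if (!is.null(schema$depth) && !is.na(schema$depth) &&
               schema$depth %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[schema$depth]]))
  } else {
    rep(NA_real_, nrow(raw))
  }
  bad_depth <- !is.na(depth) & (depth < 0 | depth > depth_max_m)
  if (any(bad_depth)) {
    warn(sprintf("%d depth values outside [0, %s] m set to NA",
                 sum(bad_depth), depth_max_m))
    depth[bad_depth] <- NA_real_
  }
  det <- tibble::tibble(
    timestamp = ts,
    receiver_id = raw[[schema$receiver]],
    transmitter_id = raw[[schema$transmitter]],
    depth_m = depth
  )
  malformed <- is.na(det$timestamp) | is.na(det$receiver_id) |
    is.na(det$transmitter_id)
  n_bad <- sum(malformed)
  if (nrow(det) > 0 && n_bad / nrow(det) > max_malformed_frac) {
    abort(sprintf("%d of %d detection rows malformed (> %.1f%% allowed)",
                  n_bad, nrow(det), 100 * max_malformed_frac))
  }
  if (n_bad > 0) {
    warn(sprintf("dropped %d malformed detection rows", n_bad))
  }
  det <- det[!malformed, , drop = FALSE]
  det <- det[order(det$timestamp, det$transmitter_id, det$receiver_id), ,
             drop = FALSE]
  det <- dplyr::distinct(det, .data$timestamp, .data$receiver_id,
                         .data$transmitter_id, .keep_all = TRUE)
  attr(det, "n_malformed") <- n_bad
  det
}

# ISO 8601 or "YYYY-mm-dd HH:MM:SS", always UTC
parse_utc <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  iso <- suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE))
  out[!is.na(iso)] <- iso[!is.na(iso)]
  out
}

#' Write normalised detections
#'
#' Inverse of [read_detections()] for the package's internal column names;
#' re-reading the written file reproduces the records field by field.
#'
#' @param detections tibble from [read_detections()] or
#'   [simulate_detections()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- detections
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read receiver deployment metadata
#'
#' One row per receiver deployment: station identity, array and reef/site
#' membership, WGS84 position and active interval. Validates coordinate
#' ranges, interval ordering and that deployments of the same receiver do
#' not overlap in time.
#'
#' @param path CSV with columns `receiver_id`, `array_id`, `site_id`,
#'   `latitude`, `longitude`, `active_from`, `active_to` and optionally
#'   `detection_radius_m` (default 250 m, the nominal detection range).
#' @param default_radius_m detection radius used when the column is absent.
#' @return A tibble of deployments.
#' @export
read_receivers <- function(path, default_radius_m = 250) {
  if (!file.exists(path)) abort(sprintf("receiver file not found: %s", path))
  rec <- readr::read_csv(path, col_types = readr::cols(
    receiver_id = "c", array_id = "c", site_id = "c",
    latitude = "d", longitude = "d",
    active_from = readr::col_date(), active_to = readr::col_date(),
    .default = "d"
  ), progress = FALSE)
  if (nrow(rec) == 0) {
    warn("receiver file is empty; returning an empty registry")
    rec$detection_radius_m <- numeric(0)
    return(rec)
  }
  if (!"detection_radius_m" %in% names(rec)) {
    rec$detection_radius_m <- default_radius_m
  }
  if (any(rec$detection_radius_m <= 0, na.rm = TRUE)) {
    abort("detection_radius_m must be positive")
  }
  if (any(rec$latitude < -90 | rec$latitude > 90, na.rm = TRUE) ||
      any(rec$longitude < -180 | rec$longitude > 180, na.rm = TRUE)) {
    abort("receiver coordinates outside valid WGS84 ranges")
  }
  if (any(rec$active_to < rec$active_from, na.rm = TRUE)) {
    bad <- rec$receiver_id[which(rec$active_to < rec$active_from)]
    abort(sprintf("active_to before active_from for receiver(s): %s",
                  paste(unique(bad), collapse = ", ")))
  }
  overlaps <- rec |>
    dplyr::arrange(.data$receiver_id, .data$active_from) |>
    dplyr::group_by(.data$receiver_id) |>
    dplyr::filter(dplyr::n() > 1,
                  .data$active_from <= dplyr::lag(.data$active_to)) |>
    dplyr::ungroup()
  if (nrow(overlaps) > 0) {
    abort(sprintf("overlapping deployments for receiver(s): %s",
                  paste(unique(overlaps$receiver_id), collapse = ", ")))
  }
  rec
}

#' Sites monitored per array
#'
#' @param receivers deployment tibble from [read_receivers()].
#' @return A tibble with one row per array: `array_id`, `n_sites`,
#'   `n_receivers`.
#' @export
receiver_sites <- function(receivers) {
  receivers |>
    dplyr::group_by(.data$array_id) |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$site_id),
                     n_receivers = dplyr::n_distinct(.data$receiver_id),
                     .groups = "drop")
}

#' Read animal tagging metadata
#'
#' @param path CSV with columns `tag_id`, `transmitter_id` (defaults to
#'   `tag_id` when absent), `sex` (`M`/`F`), `fork_length_cm`,
#'   `tagging_date`, `tagging_site`, `home_array`.
#' @return A tibble of tagged animals.
#' @export
read_tags <- function(path) {
  if (!file.exists(path)) abort(sprintf("tag file not found: %s", path))
  tags <- readr::read_csv(path, col_types = readr::cols(
    tagging_date = readr::col_date(), fork_length_cm = "d", .default = "c"
  ), progress = FALSE)
  if (!"transmitter_id" %in% names(tags)) tags$transmitter_id <- tags$tag_id
  if (!all(tags$sex %in% c("M", "F"))) abort("sex must be 'M' or 'F'")
  if (any(tags$fork_length_cm <= 0, na.rm = TRUE)) {
    abort("fork_length_cm must be positive")
  }
  tags
}

#' Read a daily environmental station series
#'
#' @param path CSV with columns `date`, `station_id`, `temperature_c`,
#'   `wind_kmh`, `rain_mm`.
#' @return A tibble with at most one row per (date, station).
#' @export
read_environment <- function(path) {
  if (!file.exists(path)) abort(sprintf("environment file not found: %s", path))
  env <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), station_id = "c", .default = "d"
  ), progress = FALSE)
  if (anyDuplicated(env[c("date", "station_id")]) > 0) {
    abort("duplicate (date, station) rows in environment file")
  }
  if (any(env$wind_kmh < 0, na.rm = TRUE) || any(env$rain_mm < 0, na.rm = TRUE)) {
    abort("wind_kmh and rain_mm must be non-negative")
  }
  env
}

#' Join detections to the deployments active at their time
#'
#' Each detection is matched to the deployment record of its receiver whose
#' active interval (in local days) covers the detection; detections at
#' unknown receivers or outside every active interval are returned as
#' rejects with a reason, not errors. `|joined| + |rejects|` always equals
#' the number of input detections.
#'
#' @param detections tibble from [read_detections()].
#' @param receivers tibble from [read_receivers()].
#' @param tz_offset_hours local-time offset applied before comparing with
#'   deployment dates (default UTC+10).
#' @return A list with elements `joined` (detections plus `array_id`,
#'   `site_id`, `latitude`, `longitude`, `detection_radius_m`) and
#'   `rejects` (detections plus `reason`).
#' @export
join_detections_to_deployments <- function(detections, receivers,
                                           tz_offset_hours = 10) {
  det <- detections
  day <- local_day(det$timestamp, tz_offset_hours)
  rid <- det$receiver_id
  # match-based lookup: almost every receiver has one deployment row, so a
  # single match() resolves the bulk; multi-deployment receivers (validated
  # non-overlapping) are searched per detection
  dep_idx <- match(rid, receivers$receiver_id)
  known <- !is.na(dep_idx)
  multi <- unique(receivers$receiver_id[duplicated(receivers$receiver_id)])
  if (length(multi) > 0) {
    rows_by_recv <- split(seq_len(nrow(receivers)), receivers$receiver_id)
    for (i in which(rid %in% multi)) {
      cand <- rows_by_recv[[rid[i]]]
      hit <- cand[receivers$active_from[cand] <= day[i] &
                  receivers$active_to[cand] >= day[i]]
      dep_idx[i] <- if (length(hit) > 0) hit[1] else NA_integer_
    }
  }
  in_window <- !is.na(dep_idx) &
    receivers$active_from[dep_idx] <= day &
    receivers$active_to[dep_idx] >= day
  in_window[is.na(in_window)] <- FALSE
  joined <- det[in_window, , drop = FALSE]
  hit_idx <- dep_idx[in_window]
  for (col in c("array_id", "site_id", "latitude", "longitude",
                "detection_radius_m")) {
    joined[[col]] <- receivers[[col]][hit_idx]
  }
  rejects <- det[!in_window, , drop = FALSE]
  rejects$reason <- ifelse(known[!in_window], "outside_deployment",
                           "unknown_receiver")
  list(joined = joined, rejects = rejects)
}
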