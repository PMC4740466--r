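#' Detect broad-scale migration events
#'
#' Scans each animal's day-level detection calendar across all arrays for
#' contiguous away-episodes: an episode opens at the first detection at a
#' non-home array (after at least one home detection, or after tagging) and
#' closes — with `returned = TRUE` — at the next home-array detection.
#' Within an episode each distinct array visited yields one *leg* with its
#' origin (the previously occupied array), so travel-time summaries can
#' exclude legs that did not depart from the home array. Day resolution:
#' away-array presence uses a single-detection threshold (sparse satellite
#' arrays rarely yield detection pairs), and a day with both home and away
#' detections is resolved home-first.
#'
#' @param ledger daily ledger from [daily_presence()] covering all arrays
#'   (every detection-day row is used, regardless of its `present` flag).
#' @param home_array home (tagging) array identifier.
#' @param tags optional tag tibble; when given, the departure date of an
#'   animal never detected at home before leaving falls back to its tagging
#'   date.
#' @return Tibble with one row per episode leg: `tag_id`, `episode`, `leg`,
#'   `origin_array`, `destination_array`, `depart` (last date at origin),
#'   `arrive` (first date at destination), `last_seen` (last date at
#'   destination within the episode), `travel_days`, `returned`.
#' @export
detect_migration_events <- function(ledger, home_array, tags = NULL) {
  empty <- tibble::tibble(tag_id = character(), episode = integer(),
                          leg = integer(), origin_array = character(),
                          destination_array = character(),
                          depart = as.Date(character()),
                          arrive = as.Date(character()),
                          last_seen = as.Date(character()),
                          travel_days = numeric(), returned = logical())
  if (nrow(ledger) == 0) return(empty)
  led <- dplyr::arrange(ledger, .data$tag_id, .data$date,
                        .data$array_id != home_array)  # home rows first in a day
  out <- lapply(split(led, led$tag_id), function(df) {
    tag <- df$tag_id[1]
    tag_date <- if (!is.null(tags)) {
      tags$tagging_date[match(tag, tags$tag_id)]
    } else {
      NA
    }
    visits <- list()
    episode <- 0L
    leg <- 0L
    open <- FALSE
    last_home <- as.Date(tag_date)
    cur_array <- NA_character_
    for (i in seq_len(nrow(df))) {
      arr <- df$array_id[i]
      day <- df$date[i]
      if (arr == home_array) {
        if (open) {
          for (j in seq_along(visits)) visits[[j]]$returned[
            visits[[j]]$episode == episode] <- TRUE
          open <- FALSE
          cur_array <- NA_character_
        }
        last_home <- day
      } else {
        if (!open) {
          episode <- episode + 1L
          leg <- 0L
          open <- TRUE
          prev_array <- home_array
          prev_date <- last_home
        }
        if (!identical(arr, cur_array)) {
          seen_before <- vapply(visits, function(v) {
            v$episode == episode && v$destination_array == arr
          }, logical(1))
          if (!any(seen_before)) {
            leg <- leg + 1L
            visits[[length(visits) + 1L]] <- tibble::tibble(
              tag_id = tag, episode = episode, leg = leg,
              origin_array = if (leg == 1L) home_array else cur_array,
              destination_array = arr,
              depart = as.Date(if (leg == 1L) prev_date else prev_leg_last),
              arrive = day, last_seen = day,
              travel_days = NA_real_, returned = FALSE)
          } else {
            k <- which(seen_before)[1]
            visits[[k]]$last_seen <- day
          }
          prev_leg_last <- day
          cur_array <- arr
        } else {
          k <- which(vapply(visits, function(v) {
            v$episode == episode && v$destination_array == arr
          }, logical(1)))[1]
          visits[[k]]$last_seen <- day
          prev_leg_last <- day
        }
      }
    }
    if (length(visits) == 0) return(empty)
    dplyr::bind_rows(visits)
  })
  ev <- dplyr::bind_rows(out)
  if (nrow(ev) == 0) return(empty)
  ev$travel_days <- as.numeric(ev$arrive - ev$depart)
  ev
}

#' One row per migration episode
#'
#' Collapses the per-leg event table to episodes; the episode's destination
#' is the first array reached.
#'
#' @param events leg table from [detect_migration_events()].
#' @return Tibble: `tag_id`, `episode`, `destination_array`, `depart`,
#'   `arrive`, `travel_days`, `returned`.
#' @export
migration_episodes <- function(events) {
  events |>
    dplyr::filter(.data$leg == 1L) |>
    dplyr::select("tag_id", "episode", "destination_array", "depart",
                  "arrive", "travel_days", "returned")
}

#' Classify the population into movers, stayers and returners
#'
#' Per-animal classification from the detected migration events: an animal
#' *moved* if it has at least one away-episode, *stayed* otherwise, and a
#' mover *returned* if every away-episode that opened also closed with a
#' home-array detection.
#'
#' @param events leg table from [detect_migration_events()].
#' @param tags tag tibble listing the whole tagged population.
#' @return A list: `per_tag` (tibble `tag_id`, `moved`, `returned`) and
#'   `proportions` (tibble with `moved`, `stayed`, `returned` as fractions
#'   of the population, plus `returned_among_migrants`).
#' @export
classify_population <- function(events, tags) {
  eps <- if (nrow(events) > 0) migration_episodes(events) else events
  per_tag <- tibble::tibble(tag_id = tags$tag_id)
  per_tag$moved <- per_tag$tag_id %in% eps$tag_id
  ret <- tapply(eps$returned, eps$tag_id, all)
  per_tag$returned <- per_tag$moved &
    unname(ret[per_tag$tag_id]) %in% TRUE
  n <- nrow(per_tag)
  n_moved <- sum(per_tag$moved)
  props <- tibble::tibble(
    moved = n_moved / n,
    stayed = 1 - n_moved / n,
    returned = sum(per_tag$returned) / n,
    returned_among_migrants = if (n_moved > 0) {
      sum(per_tag$returned) / n_moved
    } else {
      NA_real_
    }
  )
  list(per_tag = per_tag, proportions = props)
}

#' Travel-time summary to one destination array
#'
#' Range and mean +/- SD of travel days over event legs that departed the
#' home array and arrived at `destination_array`. Legs originating at other
#' arrays (multi-stop itineraries) are excluded, since their travel time
#' does not measure the home-to-destination leg. Zero-day legs (same-day
#' home and away detections) are excluded as unresolvable at day
#' resolution.
#'
#' @param events leg table from [detect_migration_events()].
#' @param destination_array destination array identifier.
#' @param home_array home array identifier.
#' @return One-row tibble: `destination_array`, `n_events`, `min_days`,
#'   `max_days`, `mean_days`, `sd_days` (`NA` for a single event).
#' @export
travel_time_summary <- function(events, destination_array, home_array) {
  legs <- events[events$origin_array == home_array &
                 events$destination_array == destination_array &
                 !is.na(events$travel_days) & events$travel_days > 0, ,
                 drop = FALSE]
  if (nrow(legs) == 0) {
    abort(sprintf("no events from %s to %s", home_array, destination_array))
  }
  td <- legs$travel_days
  tibble::tibble(destination_array = destination_array,
                 n_events = length(td), min_days = min(td),
                 max_days = max(td), mean_days = mean(td),
                 sd_days = if (length(td) > 1) sd(td) else NA_real_)
}

#' Per-array presence summary
#'
#' Summary of how many animals each array recorded and for how many days —
#' the multi-array companion to the home-array residency table. Home-array
#' day counts honour the ledger's presence rule; satellite arrays count any
#' detection day.
#'
#' @param ledger daily ledger from [daily_presence()] covering all arrays.
#' @param home_array home array identifier.
#' @param events optional leg table from [detect_migration_events()]; when
#'   given, home-departure travel-time ranges are appended per array.
#' @return Tibble per array: `array_id`, `n_sharks`, `mean_days_detected`,
#'   `sd_days_detected`, and (with events) `travel_min_days`,
#'   `travel_max_days`, `travel_mean_days`, `travel_sd_days`.
#' @export
array_presence_summary <- function(ledger, home_array, events = NULL) {
  counted <- ledger[ledger$array_id != home_array | ledger$present, ,
                    drop = FALSE]
  per_tag <- counted |>
    dplyr::group_by(.data$array_id, .data$tag_id) |>
    dplyr::summarise(days = dplyr::n_distinct(.data$date), .groups = "drop")
  out <- per_tag |>
    dplyr::group_by(.data$array_id) |>
    dplyr::summarise(n_sharks = dplyr::n(),
                     mean_days_detected = mean(.data$days),
                     sd_days_detected = if (dplyr::n() > 1) sd(.data$days)
                                        else NA_real_,
                     .groups = "drop")
  if (!is.null(events) && nrow(events) > 0) {
    tt <- events |>
      dplyr::filter(.data$origin_array == home_array,
                    !is.na(.data$travel_days), .data$travel_days > 0) |>
      dplyr::group_by(array_id = .data$destination_array) |>
      dplyr::summarise(travel_min_days = min(.data$travel_days),
                       travel_max_days = max(.data$travel_days),
                       travel_mean_days = mean(.data$travel_days),
                       travel_sd_days = if (dplyr::n() > 1) {
                         sd(.data$travel_days)
                       } else {
                         NA_real_
                       },
                       .groups = "drop")
    out <- dplyr::left_join(out, tt, by = "array_id")
  }
  out
}

#' Monthly array occupancy
#'
#' Number of distinct animals with at least one counted presence day per
#' array, month and sex (home-array days honour the presence rule;
#' satellite arrays count any detection day).
#'
#' @param ledger daily ledger from [daily_presence()].
#' @param tags tag tibble (for sex).
#' @param home_array home array identifier.
#' @return Tibble: `array_id`, `month` (first-of-month Date), `sex`,
#'   `n_individuals`.
#' @export
monthly_array_occupancy <- function(ledger, tags, home_array) {
  counted <- ledger[ledger$array_id != home_array | ledger$present, ,
                    drop = FALSE]
  counted |>
    dplyr::inner_join(tags[c("tag_id", "sex")], by = "tag_id") |>
    dplyr::mutate(month = lubridate::floor_date(.data$date, "month")) |>
    dplyr::group_by(.data$array_id, .data$month, .data$sex) |>
    dplyr::summarise(n_individuals = dplyr::n_distinct(.data$tag_id),
                     .groups = "drop")
}

#' Monthly depth-use summary
#'
#' Mean and SD of transmitter sensor depth per animal, array and month.
#'
#' @param joined detections with `tag_id`, `array_id`, `timestamp`,
#'   `depth_m`.
#' @param tz_offset_hours local-time offset for month boundaries.
#' @return Tibble: `tag_id`, `array_id`, `month`, `mean_depth_m`,
#'   `sd_depth_m`, `n_detections`; empty (with a warning) when no
#'   detections carry depth.
#' @export
monthly_depth_summary <- function(joined, tz_offset_hours = 10) {
  det <- joined[!is.na(joined$depth_m), , drop = FALSE]
  if (nrow(det) == 0) {
    warn("no depth values present; returning empty summary")
    return(tibble::tibble(tag_id = character(), array_id = character(),
                          month = as.Date(character()),
                          mean_depth_m = numeric(), sd_depth_m = numeric(),
                          n_detections = integer()))
  }
  det$month <- lubridate::floor_date(local_day(det$timestamp,
                                               tz_offset_hours), "month")
  det |>
    dplyr::group_by(.data$tag_id, .data$array_id, .data$month) |>
    dplyr::summarise(mean_depth_m = mean(.data$depth_m),
                     sd_depth_m = if (dplyr::n() > 1) sd(.data$depth_m)
                                  else NA_real_,
                     n_detections = dplyr::n(), .groups = "drop")
}
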