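#' Attach tagging metadata to joined detections
#'
#' Maps transmitter identifiers to tag identifiers and drops detections
#' dated (in local days) before the animal's tagging date, which can only
#' be tag collisions or clock errors.
#'
#' @param joined joined detections from [join_detections_to_deployments()].
#' @param tags tibble from [read_tags()].
#' @param tz_offset_hours local-time offset for day boundaries.
#' @return The joined detections with `tag_id`, `sex`, `tagging_date` and
#'   `home_array` columns added; unmatched transmitters are dropped with a
#'   warning.
#' @export
attach_tags <- function(joined, tags, tz_offset_hours = 10) {
  out <- dplyr::inner_join(
    joined,
    tags[c("tag_id", "transmitter_id", "sex", "tagging_date", "home_array")],
    by = "transmitter_id"
  )
  n_unknown <- length(setdiff(joined$transmitter_id, tags$transmitter_id))
  if (n_unknown > 0) {
    warn(sprintf("%d transmitter id(s) not in the tag register were dropped",
                 n_unknown))
  }
  pre_tag <- local_day(out$timestamp, tz_offset_hours) < out$tagging_date
  if (any(pre_tag)) {
    warn(sprintf("dropped %d detections dated before tagging", sum(pre_tag)))
    out <- out[!pre_tag, , drop = FALSE]
  }
  out
}

#' Daily presence ledger
#'
#' Collapses detections to one row per tag, local calendar day and array.
#' Under the default rule an animal is *present* in an array on a day only
#' if at least two detections on any receivers of that array fall within
#' `hour_window_s` seconds of each other on that (local) day — the standard
#' guard against single spurious code collisions. A detection pair spanning
#' midnight confers presence on neither day. The alternative rule
#' `"any_detection"` marks any detection day as present and is appropriate
#' for sparse satellite arrays where pairs are unlikely.
#'
#' @param joined detections with `tag_id` and `array_id` columns (see
#'   [attach_tags()]).
#' @param hour_window_s width of the rolling pair window in seconds
#'   (default 3600).
#' @param tz_offset_hours local-time offset for day boundaries (default
#'   UTC+10).
#' @param rule presence rule, `"pair_within_window"` (default) or
#'   `"any_detection"`.
#' @return A tibble with one row per (tag, day, array): `tag_id`, `date`,
#'   `array_id`, `n_detections`, `n_sites`, `sites` (comma-separated) and
#'   logical `present`. Days with detections that fail the rule are kept
#'   with `present = FALSE`; use [presence_days()] for the presence-only
#'   view.
#' @export
daily_presence <- function(joined, hour_window_s = 3600, tz_offset_hours = 10,
                           rule = c("pair_within_window", "any_detection")) {
  rule <- match.arg(rule)
  assert_scalar_number(hour_window_s, "hour_window_s", lower = 0)
  if (nrow(joined) == 0) {
    return(tibble::tibble(tag_id = character(), date = as.Date(character()),
                          array_id = character(), n_detections = integer(),
                          n_sites = integer(), sites = character(),
                          present = logical()))
  }
  det <- joined
  det$date <- local_day(det$timestamp, tz_offset_hours)
  det$.t <- as.numeric(det$timestamp)
  ledger <- det |>
    dplyr::arrange(.data$tag_id, .data$array_id, .data$date, .data$.t) |>
    dplyr::group_by(.data$tag_id, .data$date, .data$array_id) |>
    dplyr::summarise(
      n_detections = dplyr::n(),
      n_sites = dplyr::n_distinct(.data$site_id),
      sites = paste(sort(unique(.data$site_id)), collapse = ","),
      min_gap_s = if (dplyr::n() > 1) min(diff(.data$.t)) else Inf,
      .groups = "drop"
    )
  ledger$present <- if (rule == "pair_within_window") {
    ledger$min_gap_s <= hour_window_s
  } else {
    ledger$n_detections >= 1L
  }
  dplyr::select(ledger, -"min_gap_s")
}

#' Presence-only view of a daily ledger
#'
#' @param ledger output of [daily_presence()].
#' @return Rows of `ledger` with `present = TRUE`.
#' @export
presence_days <- function(ledger) {
  ledger[ledger$present, , drop = FALSE]
}

#' Residency index
#'
#' Days detected in an array divided by days monitored; ranges from 0
#' (never detected after tagging) to 1 (detected every monitored day).
#'
#' @param dd integer days detected, `0 <= dd <= dm`.
#' @param dm integer days monitored, `dm >= 1`.
#' @return `dd / dm`, vectorised.
#' @export
#' @examples
#' residency_index(473, 734) # 0.644
residency_index <- function(dd, dm) {
  if (any(dm < 1)) abort("days monitored must be >= 1 (undefined denominator)")
  if (any(dd < 0 | dd > dm)) abort("days detected must lie in [0, days monitored]")
  dd / dm
}

#' Days monitored
#'
#' Day-count from the tagging date to the single study-end date, both
#' endpoints inclusive — the convention under which an animal detected on
#' every monitored day (including the tagging day) has residency exactly 1,
#' and which reproduces the study's printed per-shark values with a study
#' end of 2014-10-14 (see the methods vignette). Tagging on the study-end
#' day yields the minimal monitoring span of 1 day.
#'
#' @param tagging_date Date vector.
#' @param study_end single Date, `>= tagging_date`.
#' @return Integer day counts.
#' @export
#' @examples
#' days_monitored(as.Date("2012-10-11"), as.Date("2014-10-14")) # 734
days_monitored <- function(tagging_date, study_end) {
  if (any(study_end < tagging_date)) {
    abort("study_end must not precede tagging_date")
  }
  as.integer(as.Date(study_end) - as.Date(tagging_date)) + 1L
}

#' Longest run of consecutive presence days
#'
#' @param dates a vector of presence dates (duplicates allowed).
#' @return Length of the longest run of strictly consecutive calendar
#'   days; 0 for an empty input.
#' @export
max_consecutive_days <- function(dates) {
  d <- sort(unique(as.Date(dates)))
  if (length(d) == 0) return(0L)
  runs <- rle(c(TRUE, diff(d) == 1))
  # each FALSE breaks a run; run length = count of consecutive TRUEs + 1
  breaks <- cumsum(!c(TRUE, diff(d) == 1))
  max(tabulate(breaks + 1L))
}

#' Assign residency groups from index cutpoints
#'
#' Labels animals I (high residency), II (intermediate), III (low) or IV
#' (very low) by fixed cutpoints on the residency index. With the default
#' cutpoints `{0.09, 0.20, 0.50}`: I for RI > 0.50, II for 0.20 <= RI <=
#' 0.50, III for 0.09 <= RI < 0.20, IV for RI < 0.09. The open band
#' (0.40, 0.50] — which the published group ranges leave unassigned — falls
#' to group II, its closed upper neighbour.
#'
#' @param ri residency indices in \[0, 1\].
#' @param cutpoints increasing vector of three cutpoints.
#' @return Factor with levels `I`, `II`, `III`, `IV`.
#' @export
assign_residency_groups <- function(ri, cutpoints = c(0.09, 0.20, 0.50)) {
  if (any(ri < 0 | ri > 1, na.rm = TRUE)) abort("residency index outside [0, 1]")
  if (length(cutpoints) != 3 || is.unsorted(cutpoints)) {
    abort("cutpoints must be three increasing values")
  }
  lab <- ifelse(ri > cutpoints[3], "I",
         ifelse(ri >= cutpoints[2], "II",
         ifelse(ri >= cutpoints[1], "III", "IV")))
  factor(lab, levels = c("I", "II", "III", "IV"))
}

#' Single-linkage clustering of residency indices
#'
#' Generic 1-D single-linkage hierarchical clustering of residency indices,
#' exposed for comparison with the fixed-cutpoint grouping of
#' [assign_residency_groups()]. Note that on real residency distributions
#' the two need not agree: single linkage cuts at the largest gaps in the
#' index, which may split a sparse high-residency tail before separating
#' low-residency groups (see the methods vignette).
#'
#' @param ri residency indices.
#' @param k number of clusters to cut the tree into (default 4).
#' @return A list with `cluster` (integer assignments, relabelled 1..k by
#'   decreasing cluster mean so 1 is the most resident) and `tree` (the
#'   `hclust` object, plottable as a dendrogram).
#' @export
residency_clusters <- function(ri, k = 4) {
  if (length(ri) < k) abort("need at least k residency values")
  tree <- stats::hclust(stats::dist(ri), method = "single")
  raw <- stats::cutree(tree, k = k)
  means <- tapply(ri, raw, mean)
  relabel <- setNames(rank(-means, ties.method = "first"), names(means))
  list(cluster = unname(relabel[as.character(raw)]), tree = tree)
}

#' Exclude transient animals from residency summaries
#'
#' Animals detected in their home array on fewer than `min_detection_days`
#' days most likely left the array on the day of tagging; they are excluded
#' from population residency summaries but retained for migration analysis.
#'
#' @param summaries per-animal summary tibble with a `dd` column.
#' @param min_detection_days minimum home-array detection days to keep
#'   (default 2).
#' @return A list with tibbles `kept` and `excluded`.
#' @export
exclude_transients <- function(summaries, min_detection_days = 2) {
  keep <- summaries$dd >= min_detection_days
  list(kept = summaries[keep, , drop = FALSE],
       excluded = summaries[!keep, , drop = FALSE])
}

#' Per-animal residency summary for the home array
#'
#' Builds the per-animal metric table: days monitored, days detected (under
#' the presence rule already encoded in the ledger), maximum consecutive
#' detection days, residency index and residency group.
#'
#' @param ledger daily ledger from [daily_presence()].
#' @param tags tibble from [read_tags()].
#' @param study_end single study-end date.
#' @param cutpoints passed to [assign_residency_groups()].
#' @return One row per tagged animal (zero-detection animals included):
#'   `tag_id`, `sex`, `fl_cm`, `tagging_date`, `home_array`, `dm`, `dd`,
#'   `max_dd`, `ri`, `group`.
#' @export
residency_summary <- function(ledger, tags, study_end,
                              cutpoints = c(0.09, 0.20, 0.50)) {
  pres <- presence_days(ledger)
  home <- dplyr::inner_join(pres, tags[c("tag_id", "home_array")],
                            by = "tag_id")
  home <- home[home$array_id == home$home_array, , drop = FALSE]
  per_tag <- home |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::summarise(dd = dplyr::n_distinct(.data$date),
                     max_dd = max_consecutive_days(.data$date),
                     .groups = "drop")
  out <- tags |>
    dplyr::select("tag_id", "sex", fl_cm = "fork_length_cm",
                  "tagging_date", "home_array") |>
    dplyr::left_join(per_tag, by = "tag_id") |>
    dplyr::mutate(dd = dplyr::coalesce(.data$dd, 0L),
                  max_dd = dplyr::coalesce(.data$max_dd, 0L),
                  dm = days_monitored(.data$tagging_date, study_end),
                  ri = residency_index(.data$dd, .data$dm),
                  group = assign_residency_groups(.data$ri, cutpoints))
  out
}

#' Monthly residency response table
#'
#' One row per animal and calendar month from the tagging month to the end
#' of the study: days detected, days at liberty (prorated in the tagging
#' month and the final month) and their ratio. This is the response table
#' for binomial mixed-model analyses of monthly residency, written for
#' fitting in any statistics environment.
#'
#' @param ledger daily ledger from [daily_presence()] (home-array rows are
#'   selected via `tags`).
#' @param tags tibble from [read_tags()].
#' @param study_end single study-end date.
#' @return Tibble: `tag_id`, `month` (first-of-month Date), `days_detected`,
#'   `days_at_liberty`, `proportion`.
#' @export
monthly_residency_table <- function(ledger, tags, study_end) {
  pres <- presence_days(ledger)
  pres <- dplyr::inner_join(pres, tags[c("tag_id", "home_array")],
                            by = "tag_id")
  pres <- pres[pres$array_id == pres$home_array, , drop = FALSE]
  study_end <- as.Date(study_end)
  rows <- lapply(seq_len(nrow(tags)), function(i) {
    t0 <- tags$tagging_date[i]
    months <- seq(lubridate::floor_date(t0, "month"),
                  lubridate::floor_date(study_end, "month"), by = "month")
    mstart <- pmax(months, t0)
    mend <- pmin(lubridate::ceiling_date(months, "month") - 1, study_end)
    tibble::tibble(tag_id = tags$tag_id[i], month = months,
                   days_at_liberty = as.integer(mend - mstart) + 1L)
  })
  frame <- dplyr::bind_rows(rows)
  detected <- pres |>
    dplyr::mutate(month = lubridate::floor_date(.data$date, "month")) |>
    dplyr::group_by(.data$tag_id, .data$month) |>
    dplyr::summarise(days_detected = dplyr::n_distinct(.data$date),
                     .groups = "drop")
  out <- frame |>
    dplyr::left_join(detected, by = c("tag_id", "month")) |>
    dplyr::mutate(days_detected = dplyr::coalesce(.data$days_detected, 0L),
                  proportion = .data$days_detected / .data$days_at_liberty)
  stopifnot(all(out$days_detected <= out$days_at_liberty))
  out[c("tag_id", "month", "days_detected", "days_at_liberty", "proportion")]
}

#' Population summary statistics
#'
#' Mean, SD (n - 1 denominator), minimum, maximum and n of the per-animal
#' metrics, overall and by sex. For a single animal the SD is reported as
#' `NA` (undefined under the n - 1 convention).
#'
#' @param summaries per-animal tibble (e.g. from [residency_summary()],
#'   optionally with a roaming-index column added).
#' @param metrics names of numeric columns to summarise; defaults to all of
#'   `ri`, `roi`, `fl_cm`, `max_dd`, `dd` that are present.
#' @return Long tibble: `metric`, `stratum` (`all`, `F`, `M`), `n`, `mean`,
#'   `sd`, `min`, `max`.
#' @export
population_summary <- function(summaries,
                               metrics = intersect(c("ri", "roi", "fl_cm",
                                                     "max_dd", "dd"),
                                                   names(summaries))) {
  if (nrow(summaries) < 1) abort("need at least one animal summary")
  strata <- c(list(all = summaries),
              split(summaries, summaries$sex))
  rows <- purrr::imap(strata, function(df, label) {
    purrr::map(metrics, function(m) {
      x <- df[[m]]
      tibble::tibble(metric = m, stratum = label, n = length(x),
                     mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
                     min = min(x), max = max(x))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
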