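#' Aggregate station series to a daily array-wide environment
#'
#' Unweighted mean across all stations reporting on each date; dates with
#' no reporting station are omitted.
#'
#' @param env station series from [read_environment()].
#' @return Tibble: `date`, `temperature_c`, `wind_kmh`, `rain_mm`,
#'   `n_stations_reporting` (>= 1 on every emitted row).
#' @export
aggregate_environment <- function(env) {
  env |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      n_stations_reporting = sum(!is.na(.data$temperature_c) |
                                 !is.na(.data$wind_kmh) |
                                 !is.na(.data$rain_mm)),
      temperature_c = mean(.data$temperature_c, na.rm = TRUE),
      wind_kmh = mean(.data$wind_kmh, na.rm = TRUE),
      rain_mm = mean(.data$rain_mm, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_stations_reporting >= 1)
}

#' Daily shark-count table for presence models
#'
#' The model-ready response table for daily GLM analyses of shark presence:
#' one row per date and sex over the covariate-covered study window, with
#' the number of distinct animals present in the home array that day (zero
#' rows included), a month label, and the daily environmental covariates.
#' Model fitting itself is left to standard tools (`glm`, `lme4`).
#'
#' @param ledger daily ledger from [daily_presence()].
#' @param env_daily daily environment from [aggregate_environment()].
#' @param tags tag tibble (for sex).
#' @param home_array home array identifier.
#' @param study_window optional Date vector of length 2 restricting the
#'   table; defaults to the covariate date range. Ledger dates without
#'   covariates are dropped with a warning.
#' @return Tibble: `date`, `sex`, `n_present`, `month` (factor Jan-Dec),
#'   `temperature_c`, `wind_kmh`, `rain_mm`.
#' @export
build_daily_count_table <- function(ledger, env_daily, tags, home_array,
                                    study_window = NULL) {
  pres <- presence_days(ledger)
  pres <- pres[pres$array_id == home_array, , drop = FALSE]
  window <- if (is.null(study_window)) {
    range(env_daily$date)
  } else {
    as.Date(study_window)
  }
  uncovered <- setdiff(unique(pres$date), env_daily$date)
  if (length(uncovered) > 0) {
    warn(sprintf("%d presence dates have no covariates and were dropped",
                 length(uncovered)))
  }
  frame <- tidyr::expand_grid(
    date = seq(window[1], window[2], by = "day"),
    sex = sort(unique(tags$sex))
  )
  counts <- pres |>
    dplyr::inner_join(tags[c("tag_id", "sex")], by = "tag_id") |>
    dplyr::group_by(.data$date, .data$sex) |>
    dplyr::summarise(n_present = dplyr::n_distinct(.data$tag_id),
                     .groups = "drop")
  frame |>
    dplyr::left_join(counts, by = c("date", "sex")) |>
    dplyr::mutate(n_present = dplyr::coalesce(.data$n_present, 0L),
                  month = factor(format(.data$date, "%b"), levels = month.abb)) |>
    dplyr::inner_join(env_daily[c("date", "temperature_c", "wind_kmh",
                                  "rain_mm")], by = "date")
}
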