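#' Assemble and validate a pipeline run configuration
#'
#' Either pass a YAML file path or named arguments; explicit arguments
#' override file values, and anything unset falls back to documented
#' defaults. Input paths are checked before any stage runs.
#'
#' @param config_file optional YAML file of configuration keys.
#' @param ... configuration overrides: `detections`, `receivers`, `tags`,
#'   `environment`, `sites` (input paths; `sites` optional, enables the
#'   coverage output), `out_dir`, `home_array`, `study_end`,
#'   `tz_offset_hours`, `hour_window_s`, `cutpoints`,
#'   `min_detection_days`, `matrix_level`, `matrix_mode`, `utm_zone`,
#'   `schema` (named list for [detection_schema()]).
#' @return A validated `run_config` list.
#' @export
run_config <- function(config_file = NULL, ...) {
  defaults <- list(
    detections = NULL, receivers = NULL, tags = NULL, environment = NULL,
    sites = NULL, out_dir = "results", home_array = "TSV",
    study_end = NULL, tz_offset_hours = 10, hour_window_s = 3600,
    cutpoints = c(0.09, 0.20, 0.50), min_detection_days = 2,
    matrix_level = "site", matrix_mode = "individuals", utm_zone = 55,
    schema = list(timestamp = "timestamp", receiver = "receiver_id",
                  transmitter = "transmitter_id", depth = "depth_m")
  )
  from_file <- if (!is.null(config_file)) {
    yaml::read_yaml(config_file)
  } else {
    list()
  }
  overrides <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), overrides)
  for (key in c("detections", "receivers", "tags", "environment")) {
    if (is.null(cfg[[key]])) {
      abort(sprintf("config error: input path '%s' is required", key))
    }
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("config error: %s file not found: %s", key, cfg[[key]]))
    }
  }
  if (!is.null(cfg$sites) && !file.exists(cfg$sites)) {
    abort(sprintf("config error: sites file not found: %s", cfg$sites))
  }
  if (!is.null(cfg$study_end)) cfg$study_end <- as.Date(cfg$study_end)
  structure(cfg, class = "run_config")
}

write_stage <- function(df, dir, name, counts) {
  path <- file.path(dir, name)
  readr::write_csv(df, path, progress = FALSE)
  counts[[name]] <- nrow(df)
  counts
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one input bundle: read and validate, join
#' detections to active deployments (rejects written, never fatal), build
#' the daily presence ledger, then the residency, roaming, centre-of-
#' activity, dispersal, connectivity, migration, occupancy, covariate and
#' coverage outputs, plus a run manifest with a configuration fingerprint
#' and row counts. Output bytes depend only on inputs and configuration.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  say("reading inputs")
  schema <- do.call(detection_schema, config$schema)
  detections <- read_detections(config$detections, schema = schema)
  receivers <- read_receivers(config$receivers)
  tags <- read_tags(config$tags)
  env <- read_environment(config$environment)
  study_end <- config$study_end %||% max(receivers$active_to)

  say("joining %d detections to deployments", nrow(detections))
  joined_out <- join_detections_to_deployments(detections, receivers,
                                               config$tz_offset_hours)
  joined <- attach_tags(joined_out$joined, tags, config$tz_offset_hours)
  counts <- write_stage(joined_out$rejects, config$out_dir, "rejects.csv",
                        counts)

  say("daily presence and residency")
  ledger <- daily_presence(joined, config$hour_window_s,
                           config$tz_offset_hours)
  counts <- write_stage(
    dplyr::select(presence_days(ledger), "tag_id", "date", "array_id"),
    config$out_dir, "presence_plot.csv", counts)
  summary <- residency_summary(ledger, tags, study_end, config$cutpoints)
  visits <- sites_visited(joined, config$home_array)
  n_sites <- dplyr::n_distinct(
    receivers$site_id[receivers$array_id == config$home_array])
  summary <- summary |>
    dplyr::left_join(visits, by = "tag_id") |>
    dplyr::mutate(sites_visited = dplyr::coalesce(.data$sites_visited, 0L),
                  roi = if (n_sites > 0) {
                    roaming_index(.data$sites_visited, n_sites)
                  } else {
                    NA_real_
                  })
  counts <- write_stage(summary, config$out_dir, "residency_summary.csv",
                        counts)
  counts <- write_stage(monthly_residency_table(ledger, tags, study_end),
                        config$out_dir, "monthly_residency.csv", counts)

  say("space use")
  focal <- joined[joined$array_id == config$home_array, , drop = FALSE]
  coa <- center_of_activity(focal, config$tz_offset_hours, config$utm_zone)
  counts <- write_stage(coa, config$out_dir, "coa.csv", counts)
  counts <- write_stage(dispersal_steps(coa), config$out_dir,
                        "dispersal.csv", counts)
  mm <- movement_matrix(focal, level = config$matrix_level,
                        mode = config$matrix_mode)
  counts <- write_stage(movement_matrix_long(mm), config$out_dir,
                        "movement_matrix.csv", counts)

  say("broad-scale migration")
  events <- detect_migration_events(ledger, config$home_array, tags)
  counts <- write_stage(events, config$out_dir, "migration_events.csv",
                        counts)
  counts <- write_stage(array_presence_summary(ledger, config$home_array,
                                               events),
                        config$out_dir, "array_summary.csv", counts)
  counts <- write_stage(monthly_array_occupancy(ledger, tags,
                                                config$home_array),
                        config$out_dir, "occupancy.csv", counts)

  say("covariate table")
  env_daily <- aggregate_environment(env)
  counts <- write_stage(build_daily_count_table(ledger, env_daily, tags,
                                                config$home_array),
                        config$out_dir, "daily_model_table.csv", counts)

  if (!is.null(config$sites)) {
    sites <- readr::read_csv(config$sites, col_types = readr::cols(
      site_id = "c", array_id = "c", .default = "d"), progress = FALSE)
    cov <- purrr::map(
      which(sites$array_id == config$home_array),
      function(i) {
        radii <- receivers$detection_radius_m[
          receivers$site_id == sites$site_id[i]]
        if (length(radii) == 0) return(NULL)
        out <- acoustic_coverage(sites$reef_area_km2[i], radii)
        out$site_id <- sites$site_id[i]
        out
      }) |> dplyr::bind_rows()
    counts <- write_stage(cov, config$out_dir, "coverage.csv", counts)
  }

  manifest <- list(
    package = "reefresidency",
    version = as.character(utils::packageVersion("reefresidency")),
    config_hash = fnv1a(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                         force = TRUE)),
    home_array = config$home_array,
    study_end = as.character(study_end),
    n_detections = nrow(detections),
    n_rejected = nrow(joined_out$rejects),
    n_malformed = attr(detections, "n_malformed") %||% 0L,
    row_counts = counts
  )
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: %d outputs in %s", length(counts) + 1L, config$out_dir)
  invisible(manifest)
}
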