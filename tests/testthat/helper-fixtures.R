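# In-code fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# detections tibble from timestamp strings
make_detections <- function(times, receiver = "VR2W-0001", tx = "A69-0001",
                            depth = NA_real_) {
  tibble::tibble(timestamp = utc(times),
                 receiver_id = rep_len(receiver, length(times)),
                 transmitter_id = rep_len(tx, length(times)),
                 depth_m = rep_len(depth, length(times)))
}

# minimal deployment registry: receivers at given sites/arrays, one position
# each, active over the whole window
make_receivers <- function(receiver_id, array_id, site_id,
                           latitude = -18.75, longitude = 147.05,
                           from = as.Date("2012-01-01"),
                           to = as.Date("2015-12-31"), radius = 250) {
  tibble::tibble(receiver_id = receiver_id,
                 array_id = rep_len(array_id, length(receiver_id)),
                 site_id = rep_len(site_id, length(receiver_id)),
                 latitude = rep_len(latitude, length(receiver_id)),
                 longitude = rep_len(longitude, length(receiver_id)),
                 active_from = rep_len(from, length(receiver_id)),
                 active_to = rep_len(to, length(receiver_id)),
                 detection_radius_m = rep_len(radius, length(receiver_id)))
}

make_tags <- function(tag_id, sex = "F", fl = 200,
                      tagging_date = as.Date("2012-10-08"),
                      site = "R01", home = "TSV") {
  tibble::tibble(tag_id = tag_id, transmitter_id = tag_id,
                 sex = rep_len(sex, length(tag_id)),
                 fork_length_cm = rep_len(fl, length(tag_id)),
                 tagging_date = rep(tagging_date, length.out = length(tag_id)),
                 tagging_site = rep_len(site, length(tag_id)),
                 home_array = rep_len(home, length(tag_id)))
}

# day-level ledger builder for migration tests: rows are detection-days
make_ledger <- function(tag_id, dates, arrays, present = TRUE) {
  tibble::tibble(tag_id = rep_len(tag_id, length(dates)),
                 date = as.Date(dates), array_id = arrays,
                 n_detections = 2L, n_sites = 1L, sites = "s",
                 present = rep_len(present, length(dates)))
}

schema_internal <- detection_schema("timestamp", "receiver_id",
                                    "transmitter_id", "depth_m")

# small but fully featured simulated study, cached per test session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(
        seed = 42, n_animals = 6, n_sites_focal = 6, n_receivers_focal = 12,
        study_start = as.Date("2012-10-08"), study_end = as.Date("2013-06-30"),
        tagging_spread_days = 20, migration_prob = c(F = 0.8, M = 0.5)
      )
      array <- simulate_array(cfg)
      movement <- simulate_movement(cfg, array)
      detections <- simulate_detections(movement, array, cfg)
      joined <- join_detections_to_deployments(detections,
                                               array$receivers)$joined
      joined <- attach_tags(joined, movement$tags)
      cache <<- list(cfg = cfg, array = array, movement = movement,
                     detections = detections, joined = joined)
    }
    cache
  }
})
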