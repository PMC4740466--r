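test_that("an away episode bounded by home detections is one returned event", {
  led <- make_ledger("T1",
                     c("2013-01-01", "2013-02-01", "2013-02-05", "2013-03-01"),
                     c("TSV", "ORI", "ORI", "TSV"))
  ev <- detect_migration_events(led, "TSV")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$destination_array, "ORI")
  expect_equal(ev$depart, as.Date("2013-01-01"))
  expect_equal(ev$arrive, as.Date("2013-02-01"))
  expect_equal(ev$last_seen, as.Date("2013-02-05"))
  expect_equal(ev$travel_days, 31)
  expect_true(ev$returned)
})

test_that("an episode with no later home detection stays open", {
  led <- make_ledger("T1", c("2013-01-01", "2013-02-01"), c("TSV", "HI"))
  ev <- detect_migration_events(led, "TSV")
  expect_equal(nrow(ev), 1L)
  expect_false(ev$returned)
})

test_that("home-only calendars yield no events", {
  led <- make_ledger("T1", c("2013-01-01", "2013-05-01"), c("TSV", "TSV"))
  expect_equal(nrow(detect_migration_events(led, "TSV")), 0L)
})

test_that("multi-array itineraries record per-leg origins", {
  led <- make_ledger("T1",
                     c("2013-01-01", "2013-02-01", "2013-03-01", "2013-04-01"),
                     c("TSV", "HI", "MB", "TSV"))
  ev <- detect_migration_events(led, "TSV")
  expect_equal(ev$origin_array, c("TSV", "HI"))
  expect_equal(ev$destination_array, c("HI", "MB"))
  expect_true(all(ev$returned))
  expect_equal(nrow(migration_episodes(ev)), 1L)
  # travel-time summaries only accept legs that departed the home array
  expect_error(travel_time_summary(ev, "MB", "TSV"), "no events")
  tt <- travel_time_summary(ev, "HI", "TSV")
  expect_equal(tt$n_events, 1L)
  expect_true(is.na(tt$sd_days))
})

test_that("an animal leaving before any home detection departs at tagging", {
  tags <- make_tags("T1", tagging_date = as.Date("2013-01-10"))
  led <- make_ledger("T1", c("2013-02-01"), "MB")
  ev <- detect_migration_events(led, "TSV", tags)
  expect_equal(ev$depart, as.Date("2013-01-10"))
  expect_equal(ev$travel_days, 22)
})

test_that("every away detection-day falls inside exactly one episode leg", {
  led <- dplyr::bind_rows(
    make_ledger("T1",
                c("2013-01-01", "2013-02-01", "2013-02-10", "2013-03-01",
                  "2013-11-01", "2013-11-20", "2013-12-25"),
                c("TSV", "ORI", "ORI", "TSV", "HI", "HI", "MB")),
    make_ledger("T2", c("2013-01-05", "2013-06-01"), c("TSV", "CB")))
  ev <- detect_migration_events(led, "TSV")
  away <- led[led$array_id != "TSV", ]
  for (i in seq_len(nrow(away))) {
    hits <- sum(ev$tag_id == away$tag_id[i] &
                ev$destination_array == away$array_id[i] &
                ev$arrive <= away$date[i] & ev$last_seen >= away$date[i])
    expect_equal(hits, 1L)
  }
})

test_that("population classification partitions movers and stayers", {
  tags <- make_tags(c("T1", "T2", "T3"))
  led <- dplyr::bind_rows(
    make_ledger("T1", c("2013-01-01", "2013-02-01", "2013-03-01"),
                c("TSV", "ORI", "TSV")),
    make_ledger("T2", c("2013-01-01", "2013-02-01"), c("TSV", "HI")),
    make_ledger("T3", "2013-01-01", "TSV"))
  ev <- detect_migration_events(led, "TSV", tags)
  cls <- classify_population(ev, tags)
  expect_equal(cls$proportions$moved + cls$proportions$stayed, 1)
  expect_equal(cls$proportions$moved, 2 / 3)
  expect_equal(cls$proportions$returned, 1 / 3)
  expect_equal(cls$proportions$returned_among_migrants, 1 / 2)
  # returned animals are a subset of movers
  expect_true(all(cls$per_tag$moved[cls$per_tag$returned]))
  # no events at all -> everyone stayed
  none <- classify_population(ev[0, ], tags)
  expect_equal(none$proportions$stayed, 1)
})

test_that("travel-time summaries reproduce range and spread", {
  led <- dplyr::bind_rows(
    make_ledger("T1", c("2013-01-01", "2013-01-02"), c("TSV", "CB")),
    make_ledger("T2", c("2013-01-01", "2013-01-27"), c("TSV", "CB")))
  ev <- detect_migration_events(led, "TSV")
  tt <- travel_time_summary(ev, "CB", "TSV")
  expect_equal(c(tt$min_days, tt$max_days), c(1, 26))
  expect_equal(tt$mean_days, 13.5)
  expect_equal(tt$sd_days, sd(c(1, 26)))
})

test_that("monthly occupancy counts distinct animals per array, month and sex", {
  tags <- make_tags(c("T1", "T2"), sex = c("F", "M"))
  led <- dplyr::bind_rows(
    make_ledger("T1", c("2013-12-05", "2013-12-20", "2014-01-03"),
                c("MB", "MB", "MB")),
    make_ledger("T1", "2013-12-06", "HI"),
    make_ledger("T2", c("2013-12-05", "2013-12-06"), c("TSV", "TSV")))
  occ <- monthly_array_occupancy(led, tags, "TSV")
  mb <- occ[occ$array_id == "MB", ]
  expect_equal(mb$n_individuals, c(1L, 1L))  # Dec and Jan
  # same animal in two arrays in one month counts in both
  expect_equal(occ$n_individuals[occ$array_id == "HI"], 1L)
  expect_equal(occ$sex[occ$array_id == "TSV"], "M")
})

test_that("monthly depth summaries average sensor values", {
  det <- tibble::tibble(
    timestamp = utc(c("2013-12-01 00:00:00", "2013-12-02 00:00:00",
                      "2013-12-03 00:00:00")),
    tag_id = "T1", array_id = "CR", depth_m = c(5, 10, 20))
  out <- monthly_depth_summary(det)
  expect_equal(out$mean_depth_m, mean(c(5, 10, 20)))
  out2 <- monthly_depth_summary(dplyr::mutate(det, depth_m = 5))
  expect_equal(out2$mean_depth_m, 5)
  expect_warning(empty <- monthly_depth_summary(
    dplyr::mutate(det, depth_m = NA_real_)), "no depth")
  expect_equal(nrow(empty), 0L)
})

test_that("array presence summary separates home-rule and away-rule days", {
  led <- dplyr::bind_rows(
    make_ledger("T1", c("2013-01-01", "2013-01-02"), c("TSV", "TSV"),
                present = c(TRUE, FALSE)),  # second day fails the pair rule
    make_ledger("T1", "2013-02-01", "ORI", present = FALSE))
  out <- array_presence_summary(led, "TSV")
  expect_equal(out$mean_days_detected[out$array_id == "TSV"], 1)
  # the satellite day still counts under the one-detection threshold
  expect_equal(out$n_sharks[out$array_id == "ORI"], 1L)
})
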