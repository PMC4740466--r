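# joined-detections builder at explicit UTM positions (zone 55S)
joined_at <- function(easting, northing, times, tag = "T1", site = "R01") {
  geo <- utm_to_lonlat(easting, northing)
  tibble::tibble(timestamp = utc(times), tag_id = tag, array_id = "TSV",
                 site_id = rep_len(site, length(times)),
                 latitude = geo$latitude, longitude = geo$longitude)
}

test_that("UTM projection round-trips within a metre and is deterministic", {
  lon <- seq(144.5, 149.5, by = 0.5)
  lat <- seq(-28, -12, length.out = length(lon))
  fwd <- project_to_utm(lon, lat)
  back <- utm_to_lonlat(fwd$easting, fwd$northing)
  fwd2 <- project_to_utm(back$longitude, back$latitude)
  err_m <- sqrt((fwd2$easting - fwd$easting)^2 +
                (fwd2$northing - fwd$northing)^2)
  expect_true(all(err_m < 1))
  expect_identical(project_to_utm(147.05, -18.75),
                   project_to_utm(147.05, -18.75))
  expect_error(project_to_utm(NaN, -18), "finite")
})

test_that("projected northings match the independent geodesic oracle", {
  # 0.01 degrees of latitude is ~1105 m of meridian arc
  a <- project_to_utm(147.05, -18.75)
  b <- project_to_utm(147.05, -18.74)
  dn <- b$northing - a$northing
  expect_true(abs(dn - 1105) < 5)
  skip_if_not_installed("geosphere")
  geo <- geosphere::distGeo(c(147.05, -18.75), c(147.05, -18.74))
  expect_lt(abs(dn - geo), 2)
})

test_that("centre of activity is the detection-weighted mean receiver position", {
  # all detections at one receiver -> its position
  coa <- center_of_activity(joined_at(500000, 7926000,
                                      c("2013-01-01 00:00:00",
                                        "2013-01-01 00:10:00")))
  expect_equal(coa$easting, 500000, tolerance = 1e-6)
  expect_equal(coa$northing, 7926000, tolerance = 1e-6)
  expect_equal(coa$n_detections, 2L)
  # equal counts at two receivers -> midpoint
  df <- dplyr::bind_rows(
    joined_at(500000, 7926000, "2013-01-01 00:00:00"),
    joined_at(502000, 7926000, "2013-01-01 00:20:00", site = "R02"))
  coa <- center_of_activity(df)
  expect_equal(coa$easting, 501000, tolerance = 1e-6)
  # counts 3 and 1 four km apart -> quarter point
  df <- dplyr::bind_rows(
    joined_at(500000, 7926000, sprintf("2013-01-01 00:0%d:00", 1:3)),
    joined_at(500000, 7930000, "2013-01-01 00:30:00", site = "R02"))
  coa <- center_of_activity(df)
  expect_equal(coa$northing, 7927000, tolerance = 1e-6)
  # detections an hour apart land in distinct clock-hour bins
  df <- joined_at(500000, 7926000, c("2013-01-01 00:10:00",
                                     "2013-01-01 01:10:00"))
  expect_equal(nrow(center_of_activity(df)), 2L)
})

test_that("COA positions stay inside the receiver bounding box on simulated tracks", {
  sim <- small_sim()
  focal <- sim$joined[sim$joined$array_id == "TSV", ]
  coa <- center_of_activity(focal)
  utm <- project_to_utm(focal$longitude, focal$latitude)
  eps <- 1e-6
  expect_true(all(coa$easting >= min(utm$easting) - eps &
                  coa$easting <= max(utm$easting) + eps))
  expect_true(all(coa$northing >= min(utm$northing) - eps &
                  coa$northing <= max(utm$northing) + eps))
})

test_that("dispersal steps report straight-line km between consecutive COAs", {
  df <- dplyr::bind_rows(
    joined_at(500000, 7926000, c("2013-01-01 00:00:00",
                                 "2013-01-01 00:01:00")),
    joined_at(503000, 7930000, "2013-01-01 02:30:00", site = "R02"))
  steps <- dispersal_steps(center_of_activity(df))
  expect_equal(steps$distance_km, 5)  # 3-4-5 triangle
  expect_equal(steps$elapsed_h, 2)
  # single COA -> no steps
  one <- center_of_activity(joined_at(500000, 7926000, "2013-01-01 00:00:00"))
  expect_equal(nrow(dispersal_steps(one)), 0L)
  # stationary animal: zero distance, positive elapsed time
  df <- joined_at(500000, 7926000, c("2013-01-01 00:00:00",
                                     "2013-01-01 03:00:00",
                                     "2013-01-01 07:00:00"))
  steps <- dispersal_steps(center_of_activity(df))
  expect_true(all(steps$distance_km == 0))
  expect_true(all(steps$elapsed_h > 0))
})

test_that("roaming index is reefs visited over reefs monitored", {
  expect_equal(round_half_up(roaming_index(11, 17), 2), 0.65)
  expect_equal(round_half_up(roaming_index(2, 17), 2), 0.12)
  expect_equal(roaming_index(17, 17), 1)
  expect_error(roaming_index(1, 0), "monitored")
  expect_error(roaming_index(18, 17), "sites_visited")
})

test_that("movement matrix counts individuals or moves over collapsed runs", {
  df <- tibble::tibble(
    timestamp = utc("2013-01-01 00:00:00") + (0:4) * 3600,
    tag_id = "T1", array_id = "TSV",
    site_id = c("A", "A", "B", "B", "A"))
  m <- movement_matrix(df, level = "site")
  expect_equal(m["A", "B"], 1L)
  expect_equal(m["B", "A"], 1L)
  expect_equal(sum(m), 2L)
  # two animals A -> B counted twice in individuals mode
  df2 <- dplyr::bind_rows(df, dplyr::mutate(df, tag_id = "T2"))
  m2 <- movement_matrix(df2, level = "site")
  expect_equal(m2["A", "B"], 2L)
  # moves mode counts repeated transitions
  df3 <- tibble::tibble(
    timestamp = utc("2013-01-01 00:00:00") + (0:3) * 3600,
    tag_id = "T1", array_id = "TSV", site_id = c("A", "B", "A", "B"))
  expect_equal(movement_matrix(df3, mode = "moves")["A", "B"], 2L)
  expect_equal(movement_matrix(df3, mode = "individuals")["A", "B"], 1L)
  # no site change -> empty off-diagonal
  still <- dplyr::mutate(df, site_id = "A")
  expect_equal(sum(movement_matrix(still)), 0L)
  # long export drops zero cells and keeps counts
  long <- movement_matrix_long(m)
  expect_equal(sum(long$count), sum(m))
})

test_that("shelf-position frequencies partition all moves into percentages", {
  df <- tibble::tibble(
    timestamp = utc("2013-01-01 00:00:00") + (0:3) * 3600,
    tag_id = "T1", array_id = "TSV", site_id = c("A", "B", "C", "A"))
  labels <- c(A = "inner", B = "inner", C = "outer")
  m <- movement_matrix(df, mode = "moves")
  freq <- shelf_position_frequencies(m, labels)
  expect_equal(sum(freq), 100)
  expect_equal(attr(freq, "n_moves"), sum(m))  # conservation
  # all-inner moves give 100% inner->inner
  inner_only <- movement_matrix(
    dplyr::mutate(df, site_id = c("A", "B", "A", "B")), mode = "moves")
  freq <- shelf_position_frequencies(inner_only, labels)
  expect_equal(freq["inner", "inner"], 100)
  expect_error(shelf_position_frequencies(m, labels[-3]), "unlabelled")
  empty <- movement_matrix(df[1, ], mode = "moves")
  expect_error(shelf_position_frequencies(empty, labels), "no moves")
})

test_that("acoustic coverage is capped disc area over reef area", {
  # one 250 m receiver exactly covers a reef of pi * 0.25^2 km2
  cov <- acoustic_coverage(pi * 0.25^2, 250)
  expect_equal(cov$coverage_fraction, 1)
  expect_equal(acoustic_coverage(19.635, c(250, 250))$coverage_fraction,
               0.02, tolerance = 1e-3)
  # dense receivers saturate at 1
  expect_equal(acoustic_coverage(0.1, rep(300, 10))$coverage_fraction, 1)
  expect_error(acoustic_coverage(19.6, 0), "positive")
  expect_error(acoustic_coverage(-1, 250), "positive")
})

test_that("dispersal distances obey the triangle inequality on simulated tracks", {
  sim <- small_sim()
  focal <- sim$joined[sim$joined$array_id == "TSV", ]
  coa <- center_of_activity(focal)
  per_tag <- split(coa, coa$tag_id)
  for (tr in per_tag) {
    if (nrow(tr) < 3) next
    d <- function(i, j) sqrt((tr$easting[i] - tr$easting[j])^2 +
                             (tr$northing[i] - tr$northing[j])^2)
    idx <- seq_len(nrow(tr) - 2)
    expect_true(all(d(idx, idx + 2) <= d(idx, idx + 1) + d(idx + 1, idx + 2)
                    + 1e-9))
  }
})
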