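joined_row <- function(times, tag = "T1", array = "TSV", site = "R01") {
  tibble::tibble(timestamp = utc(times), tag_id = tag, array_id = array,
                 site_id = site)
}

test_that("daily presence needs two detections within the hour window on one local day", {
  # two detections 30 min apart -> present
  led <- daily_presence(joined_row(c("2013-01-01 00:00:00",
                                     "2013-01-01 00:30:00")))
  expect_true(led$present)
  # a single detection is not presence
  led <- daily_presence(joined_row("2013-01-01 00:00:00"))
  expect_false(led$present)
  # 90 min apart, nothing else -> absent
  led <- daily_presence(joined_row(c("2013-01-01 00:00:00",
                                     "2013-01-01 01:30:00")))
  expect_false(led$present)
  # the pair may span receivers of the same array
  df <- joined_row(c("2013-01-01 02:00:00", "2013-01-01 02:10:00"),
                   site = c("R01", "R02"))
  expect_true(daily_presence(df)$present)
  # a qualifying pair across local midnight confers presence on neither day
  # (local midnight = 14:00 UTC at UTC+10)
  df <- joined_row(c("2013-01-01 13:50:00", "2013-01-01 14:10:00"))
  led <- daily_presence(df)
  expect_equal(nrow(led), 2L)
  expect_false(any(led$present))
  # under the any-detection rule single detections count
  expect_true(all(daily_presence(df, rule = "any_detection")$present))
})

test_that("presence is monotone: extra detections never remove a presence day", {
  base <- joined_row(sprintf("2013-01-0%d 0%d:00:00", rep(1:3, each = 2),
                             c(1, 5, 1, 3, 2, 2)))
  before <- presence_days(daily_presence(base))
  more <- dplyr::bind_rows(base,
                           joined_row(c("2013-01-01 11:00:00",
                                        "2013-01-04 07:00:00",
                                        "2013-01-04 07:30:00")))
  after <- presence_days(daily_presence(more))
  expect_true(all(before$date %in% after$date))
})

test_that("residency index is the detected/monitored ratio with guarded bounds", {
  expect_equal(round_half_up(residency_index(473, 734), 2), 0.64)
  expect_equal(residency_index(0, 100), 0)
  expect_equal(residency_index(100, 100), 1)
  expect_error(residency_index(1, 0), "denominator")
  expect_error(residency_index(5, 4), "days detected")
  ri <- residency_index(0:10, rep(10, 11))
  expect_true(all(ri >= 0 & ri <= 1))
})

test_that("days monitored reproduces the published per-shark spans", {
  end <- as.Date("2014-10-14")
  tagged <- as.Date(c("2012-10-08", "2012-10-11", "2013-02-11",
                      "2014-02-15", "2014-02-19"))
  expect_equal(days_monitored(tagged, end), c(737L, 734L, 611L, 242L, 238L))
  expect_equal(days_monitored(end, end), 1L)
  expect_error(days_monitored(end + 1, end), "precede")
})

test_that("max consecutive days matches a brute-force subrange scan", {
  expect_equal(max_consecutive_days(as.Date(character())), 0L)
  d <- as.Date("2013-05-01")
  expect_equal(max_consecutive_days(c(d, d + 1, d + 2, d + 10)), 3L)
  expect_equal(max_consecutive_days(d), 1L)

  brute_force <- function(dates) {
    d <- sort(unique(dates))
    if (length(d) == 0) return(0L)
    best <- 0L
    for (a in seq_along(d)) for (b in a:length(d)) {
      span <- seq(d[a], d[b], by = "day")
      if (all(span %in% d)) best <- max(best, length(span))
    }
    best
  }
  set.seed(11)
  for (i in 1:60) {
    dates <- as.Date("2013-01-01") + sample(0:60, sample(0:25, 1))
    expect_equal(max_consecutive_days(dates), brute_force(dates))
  }
})

test_that("cutpoint grouping reproduces the published four residency groups", {
  sharks <- bull_shark_summaries()
  kept <- exclude_transients(sharks)$kept
  groups <- assign_residency_groups(kept$ri)
  expect_equal(as.vector(table(groups)), c(4L, 8L, 8L, 12L))
  # every kept shark gets exactly one label
  expect_false(anyNA(groups))
  expect_equal(length(groups), nrow(kept))
  # the single most resident example shark lands in group I
  expect_equal(as.character(groups[kept$tag_id == "T4"]), "I")
  expect_true(all(assign_residency_groups(rep(0, 5)) == "IV"))
  expect_error(assign_residency_groups(1.2), "outside")
})

test_that("single-linkage clustering recovers well-separated residency groups", {
  ri <- c(0.70, 0.72, 0.71, 0.40, 0.41, 0.42, 0.05, 0.06, 0.04)
  out <- residency_clusters(ri, k = 3)
  expect_equal(out$cluster, rep(c(1L, 2L, 3L), each = 3))
  expect_s3_class(out$tree, "hclust")
})

test_that("transient animals are excluded from residency but kept elsewhere", {
  sharks <- bull_shark_summaries()
  split <- exclude_transients(sharks)
  expect_equal(split$excluded$tag_id, "T33")  # detected a single day
  expect_equal(nrow(split$kept), 32L)
  expect_true(all(split$kept$dd >= 2))
  empty <- exclude_transients(sharks[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$excluded), 0L)
})

test_that("monthly residency prorates the tagging month", {
  tags <- make_tags("T1", tagging_date = as.Date("2013-01-15"))
  # present every day from tagging through February
  dates <- seq(as.Date("2013-01-15"), as.Date("2013-02-28"), by = "day")
  ledger <- make_ledger("T1", dates, rep("TSV", length(dates)))
  tab <- monthly_residency_table(ledger, tags, as.Date("2013-03-31"))
  jan <- tab[tab$month == as.Date("2013-01-01"), ]
  feb <- tab[tab$month == as.Date("2013-02-01"), ]
  mar <- tab[tab$month == as.Date("2013-03-01"), ]
  expect_equal(jan$days_at_liberty, 17L)  # 15-31 Jan
  expect_equal(jan$proportion, 1)
  expect_equal(feb$proportion, 1)
  expect_equal(mar$proportion, 0)
  # at-liberty days over all months add up to the monitored span
  expect_equal(sum(tab$days_at_liberty),
               days_monitored(tags$tagging_date, as.Date("2013-03-31")))
  expect_true(all(tab$days_detected <= tab$days_at_liberty))
})

test_that("population summary reports n-1 SDs and flags single-animal strata", {
  sharks <- bull_shark_summaries()
  kept <- exclude_transients(sharks)$kept
  pop <- population_summary(kept, metrics = c("ri", "fl_cm"))
  ri_all <- pop[pop$metric == "ri" & pop$stratum == "all", ]
  expect_equal(ri_all$n, 32L)
  expect_equal(ri_all$mean, mean(kept$ri))
  expect_equal(ri_all$sd, sd(kept$ri))
  one <- population_summary(kept[1, ], metrics = "ri")
  expect_true(all(is.na(one$sd)))
  expect_equal(one$mean[1], kept$ri[1])
})
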