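test_that("clock bins are half-open and tile the day", {
  expect_equal(assign_bin(c("09:00", "11:59", "12:00", "00:00", "23:59")),
               c(3L, 3L, 4L, 0L, 7L))
  expect_equal(assign_bin(as.POSIXct("2020-06-01 15:00:00", tz = "UTC")), 5L)
  # tiling: every minute of the day maps to exactly one bin, 180 each
  bins <- assign_bin(0:1439)
  expect_equal(as.vector(table(bins)), rep(180L, 8))
  expect_equal(sort(unique(bins)), 0:7)
  expect_error(assign_bin(1440L), "minute-of-day")
  expect_equal(daytime_bins(), 3:6)
})

test_that("interval summaries are conserving and localized", {
  # activity only between 15:00 and 18:00, rest of day zero
  counts <- integer(1440)
  counts[(15 * 60 + 1):(18 * 60)] <- 500L
  ep <- data.table(participant_id = "A", visit = "baseline",
                   date = as.IDate("2020-01-01") + rep(0:3, each = 1440),
                   minute = rep(0:1439, 4),
                   counts = rep(counts, 4), steps = 0L)
  wear <- validate_wear(ep)
  # the quiet remainder of each day is detected as non-wear, so these days
  # fail the 10-h rule; keep them to exercise the bin accounting
  ints <- summarize_intervals(ep, wear, include_invalid_days = TRUE)
  expect_equal(nrow(ints), 8L)
  expect_equal(ints[bin == 5]$total_counts, 180 * 500)
  expect_equal(ints[bin != 5]$total_counts, rep(0, 7))
  # bin minutes + non-wear minutes tile each 180-min bin
  expect_equal(ints$sed_min + ints$lpa_min + ints$mvpa_min +
                 1.8 * ints$nonwear_pct,
               rep(180, 8))
})

test_that("bin-level totals aggregate to day-level totals", {
  co <- generate_cohort(cohort_spec(n_participants = 3, seed = 77))
  pl <- run_pipeline(co)
  by_visit <- pl$intervals[, .(total_counts = sum(total_counts),
                               sed_min = sum(sed_min),
                               lpa_min = sum(lpa_min),
                               mvpa_min = sum(mvpa_min)),
                           by = .(participant_id, visit)]
  m <- merge(by_visit, pl$visits, by = c("participant_id", "visit"),
             suffixes = c("_bins", "_day"))
  expect_equal(m$total_counts_bins, m$total_counts_day)
  expect_equal(m$sed_min_bins, m$sed_min_day)
  expect_equal(m$lpa_min_bins, m$lpa_min_day)
  expect_equal(m$mvpa_min_bins, m$mvpa_min_day)
})

test_that("interval change scores difference the visits and flag zero baselines", {
  ints <- data.table(
    participant_id = "A",
    visit = rep(c("baseline", "followup"), each = 2),
    bin = c(3L, 4L, 3L, 4L),
    total_counts = c(100, 0, 79, 5),
    total_steps = 0, sed_min = c(10, 10, 10, 10), lpa_min = 0,
    mvpa_min = 0, nonwear_pct = 0
  )
  chg <- interval_change(ints)
  r3 <- chg[bin == 3L]
  expect_equal(r3$total_counts_change, -21)
  expect_equal(r3$total_counts_pct, -21)
  expect_equal(r3$sed_min_change, 0)
  # zero baseline: absolute change reported, percent flagged NA
  r4 <- chg[bin == 4L]
  expect_equal(r4$total_counts_change, 5)
  expect_true(is.na(r4$total_counts_pct))

  # identical visits give all-zero changes
  same <- copy(ints)[visit == "followup",
                     total_counts := c(100, 0)]
  chg0 <- interval_change(same)
  expect_equal(chg0$total_counts_change, c(0, 0))
})
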