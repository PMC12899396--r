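test_that("non-wear detection handles canonical day patterns", {
  # all-zero day: a single interval covering the day
  iv <- detect_nonwear(rep(0L, 1440))
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 1L)
  expect_equal(iv$end, 1441L)
  expect_equal(wear_minutes(rep(0L, 1440), iv), 0L)

  # one sub-threshold interruption inside 90 zeros qualifies (91 min)
  x <- c(rep(500L, 5), rep(0L, 45), 50L, rep(0L, 45), rep(500L, 5))
  iv <- detect_nonwear(x)
  expect_equal(iv$length, 91L)
  expect_equal(iv$start, 6L)
  expect_equal(x[iv$start], 0L)
  expect_equal(x[iv$end - 1L], 0L)

  # an epoch at the threshold breaks the window; each zero run is < 90
  expect_equal(nrow(detect_nonwear(c(rep(0L, 60), 150L, rep(0L, 60)))), 0L)

  # three interruptions exceed the allowance
  expect_equal(nrow(detect_nonwear(c(rep(0L, 45), 50L, 60L, 70L,
                                     rep(0L, 45)))), 0L)
})

test_that("wear minutes are the complement of detected non-wear", {
  active <- rep(500L, 1440)
  expect_equal(wear_minutes(active), 1440L)
  one_iv <- c(rep(500L, 600), rep(0L, 91), rep(500L, 749))
  expect_equal(wear_minutes(one_iv), 1349L)
})

test_that("detection matches the definition-based oracles", {
  set.seed(4821)
  for (r in 1:300) {
    x <- random_count_sequence(250L)
    got <- as.data.frame(detect_nonwear(x))
    expect_identical(got, oracle_nonwear_brute(x))
    expect_identical(got, oracle_nonwear_enum(x))
  }
})

test_that("detection is idempotent, monotone in the window length, and conserving", {
  set.seed(911)
  for (r in 1:60) {
    x <- random_count_sequence(1500L)
    iv <- detect_nonwear(x)
    covered <- rep(FALSE, length(x))
    for (i in seq_len(nrow(iv))) covered[iv$start[i]:(iv$end[i] - 1L)] <- TRUE

    # conservation
    expect_equal(wear_minutes(x, iv) + sum(iv$length), length(x))
    expect_equal(sum(!wear_mask(x)), sum(iv$length))

    # idempotence: zeroing detected epochs can only grow coverage
    x2 <- x
    x2[covered] <- 0L
    iv2 <- detect_nonwear(x2)
    covered2 <- rep(FALSE, length(x))
    for (i in seq_len(nrow(iv2))) covered2[iv2$start[i]:(iv2$end[i] - 1L)] <- TRUE
    expect_true(all(covered2[covered]))

    # shorter minimum window never detects less
    expect_gte(sum(detect_nonwear(x, min_window_min = 60L)$length),
               sum(iv$length))
  }
})

test_that("detection validates its inputs", {
  expect_error(detect_nonwear(c(0L, -5L)), "non-negative")
  expect_error(detect_nonwear(integer(0)), "at least one")
})

test_that("valid-day rule is inclusive at 10 hours of wear", {
  day600 <- data.table::data.table(date = as.Date("2020-01-01"),
                                   minute = 0:1439,
                                   counts = c(rep(0L, 840), rep(500L, 600)))
  v <- valid_days(day600)
  expect_equal(v$wear_min, 600L)
  expect_true(v$valid)

  day599 <- data.table::data.table(date = as.Date("2020-01-01"),
                                   minute = 0:1439,
                                   counts = c(rep(0L, 841), rep(500L, 599)))
  v <- valid_days(day599)
  expect_equal(v$wear_min, 599L)
  expect_false(v$valid)

  expect_equal(nrow(valid_days(day600[0])), 0L)
})

test_that("valid-participant rule includes 4-7 valid days and rejects >7 recorded days", {
  mk <- function(valid) data.table::data.table(
    date = as.Date("2020-01-01") + seq_along(valid) - 1, valid = valid)
  expect_true(valid_participant(mk(rep(TRUE, 4)))$included)
  expect_false(valid_participant(mk(c(rep(TRUE, 3), FALSE)))$included)
  expect_true(valid_participant(mk(rep(TRUE, 7)))$included)
  expect_false(valid_participant(mk(rep(FALSE, 7)))$included)
  expect_error(valid_participant(mk(rep(TRUE, 8))), "more than 7")
})

test_that("validate_wear agrees with per-day detection and flags participants", {
  set.seed(7)
  co <- generate_cohort(cohort_spec(n_participants = 3, seed = 31))
  wear <- validate_wear(co$epochs)
  expect_equal(length(wear$worn), nrow(co$epochs))

  # spot-check one participant-day against the single-day API
  one <- co$epochs[participant_id == "P00002" & visit == "baseline"]
  d1 <- one[date == min(date)]
  expect_equal(
    wear$days[participant_id == "P00002" & visit == "baseline" &
                date == min(date)]$wear_min,
    sum(wear_mask(d1$counts)))

  expect_equal(nrow(wear$participants), 6L)
  expect_true(all(wear$participants$n_valid_days <= 7L))
})
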