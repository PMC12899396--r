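test_that("spec validation names the offending field", {
  expect_error(cohort_spec(-1), "n_participants")
  expect_error(cohort_spec(10, worsening_fraction = 1.2), "worsening_fraction")
  expect_error(cohort_spec(10, diurnal_profile = rep(-1, 24)), "diurnal_profile")
  expect_error(cohort_spec(10, decline_effects = list(stable = rep(0, 8),
                                                      worsening = rep(1, 8))),
               "decline_effects")
  expect_error(cohort_spec(10, epoch_seconds = 30), "epoch_seconds")
  expect_error(cohort_spec(10, nonwear_model = list(
    overnight_start = 25, overnight_end = 7, daytime_rate = 0.3,
    daytime_mean_min = 150, daytime_shape = 6)), "nonwear_model")
})

test_that("an empty cohort is empty, not an error", {
  co <- generate_cohort(cohort_spec(n_participants = 0, seed = 3))
  expect_equal(nrow(co$epochs), 0L)
  expect_equal(nrow(co$clinical), 0L)
  expect_equal(length(co$truth$nonwear), 0L)
})

test_that("identical seeds give bit-identical cohorts", {
  s <- cohort_spec(n_participants = 3, seed = 7)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$epochs, b$epochs)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$nonwear, b$truth$nonwear)
  # and the generator restores the caller's RNG state
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_cohort(s)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated epochs honour the protocol structure and ground truth", {
  co <- generate_cohort(cohort_spec(n_participants = 4, seed = 21))
  ep <- co$epochs
  expect_equal(nrow(ep), 4 * 2 * 7 * 1440)
  per_day <- ep[, .N, by = .(participant_id, visit, date)]
  expect_true(all(per_day$N == 1440L))
  expect_equal(nrow(per_day), 4 * 2 * 7)
  expect_true(all(ep$counts >= 0L))

  # true non-wear is always recorded as zero counts and zero steps
  expect_true(all(ep$counts[co$truth$nonwear] == 0L))
  expect_true(all(ep$steps[co$truth$nonwear] == 0L))

  # steps: zero iff counts zero is not required, but zero counts force
  # zero steps, and the cadence cap holds
  expect_true(all(ep$steps[ep$counts == 0L] == 0L))
  expect_true(all(ep$steps <= 130L))

  # group labels are functionally determined by the drawn WOMAC change
  tr <- co$truth$groups
  expect_true(all((tr$womac_change > 10) == (tr$group == "worsening")))
  cl <- dcast(co$clinical, participant_id ~ visit, value.var = "womac_total")
  got <- classify_group(cl$baseline, cl$followup)
  expect_equal(as.character(got), tr$group[match(cl$participant_id,
                                                 tr$participant_id)])
})

test_that("epoch CSV round-trips losslessly", {
  co <- generate_cohort(cohort_spec(n_participants = 2, n_days_per_visit = 1,
                                    seed = 10))
  path <- tempfile(fileext = ".csv")
  write_epoch_csv(co$epochs, path)
  back <- read_epoch_csv(path)
  expect_equal(back, co$epochs, ignore_attr = TRUE)
  # one participant-visit-day contributes exactly 1440 data rows
  expect_equal(length(readLines(path)) - 1L, nrow(co$epochs))

  # empty series: header-only file reads back empty
  write_epoch_csv(co$epochs[0], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_epoch_csv(path)), 0L)

  # clinical table round-trip
  write_clinical_csv(co$clinical, path)
  back <- read_clinical_csv(path)
  expect_equal(back$womac_total, co$clinical$womac_total)
})

test_that("daily intensity composition lands near the generator targets", {
  spec <- cohort_spec(n_participants = 100, seed = 2024)
  co <- generate_cohort(spec)
  wear <- validate_wear(co$epochs)
  visits <- summarize_visits(summarize_days(co$epochs, wear), wear)
  vb <- visits[visit == "baseline"]
  expect_gte(nrow(vb), 90)
  tgt <- spec$intensity_mix
  expect_lt(abs(mean(vb$sed_min) - tgt[["sed"]]) / tgt[["sed"]], 0.2)
  expect_lt(abs(mean(vb$lpa_min) - tgt[["lpa"]]) / tgt[["lpa"]], 0.2)
  expect_lt(abs(mean(vb$mvpa_min) - tgt[["mvpa"]]) / tgt[["mvpa"]], 0.2)
})
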