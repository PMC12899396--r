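test_that("MCID grouping uses a strict >10 increase and is shift-invariant", {
  expect_equal(as.character(classify_group(10.8, 10.8 + 19.6)), "worsening")
  expect_equal(as.character(classify_group(12, 12 - 1.9)), "stable")
  expect_equal(as.character(classify_group(5, 15)), "stable")       # exactly +10
  expect_equal(as.character(classify_group(30, 10)), "stable")      # improvement
  expect_equal(as.character(classify_group(5, 15.01)), "worsening")
  expect_error(classify_group(NA, 12), "present")

  # shift invariance: adding a constant to both scores never flips the label
  set.seed(12)
  b <- runif(200, 0, 60)
  f <- b + runif(200, -20, 30)
  k <- runif(200, -5, 5)
  expect_equal(classify_group(b, f), classify_group(b + k, f + k))
})

test_that("worse-knee selection follows KL, then JSW, then the right-knee tie-break", {
  expect_equal(select_worse_knee(3, 2, 3.5, 4.0), "left")
  expect_equal(select_worse_knee(2, 3, 3.5, 4.0), "right")
  expect_equal(select_worse_knee(2, 2, 3.5, 4.0), "left")   # smaller JSW
  expect_equal(select_worse_knee(2, 2, 4.0, 3.5), "right")
  expect_equal(select_worse_knee(2, 2, 4.0, 4.0), "right")  # double tie
  expect_equal(select_worse_knee(2, 2, NA, 3.5), "right")   # JSW cannot break
  expect_error(select_worse_knee(NA, 2), "KL")
  expect_equal(select_worse_knee(c(3, 2), c(2, 2), c(4, 4), c(4, 3.9)),
               c("left", "right"))
})

test_that("JSW imputation averages adjacent observed visits only", {
  expect_equal(impute_jsw(c(3.8, NA, 3.6)), c(3.8, 3.7, 3.6))
  expect_equal(impute_jsw(c(NA, 3.8, 4.0)), c(3.8, 3.8, 4.0))
  expect_equal(impute_jsw(c(NA, NA, NA)), c(NA_real_, NA_real_, NA_real_))
  # convex hull: an imputed value never leaves its neighbours' range
  set.seed(5)
  for (r in 1:50) {
    x <- runif(6, 1, 6)
    x[sample(6, 2)] <- NA
    y <- impute_jsw(x)
    for (i in which(is.na(x) & !is.na(y))) {
      adj <- c(if (i > 1) x[i - 1], if (i < 6) x[i + 1])
      adj <- adj[!is.na(adj)]
      expect_gte(y[i], min(adj))
      expect_lte(y[i], max(adj))
    }
  }
})

test_that("KL carry-forward uses the most recent earlier grade", {
  expect_equal(carry_forward_kl(c(2, NA)), c(2, 2))
  expect_equal(carry_forward_kl(c(NA, 3)), c(NA, 3))
  expect_equal(carry_forward_kl(c(1, NA, NA)), c(1, 1, 1))
  expect_equal(carry_forward_kl(c(1, NA, 3, NA)), c(1, 1, 3, 3))
})

test_that("exclusion cascade tags each participant with the first applying reason", {
  mk <- function(id, kr = FALSE, kl = 2L, bmi = 25, womac_f = 12) rbind(
    data.table(participant_id = id, visit = "baseline", age = 60,
               sex = "female", race = "white", bmi = bmi, womac_total = 10,
               cesd = 5, pase = 150, gait_speed = 1.3, fts = 10, falls = 0L,
               kl_left = kl, kl_right = kl, jsw_left = 4, jsw_right = 4,
               knee_replacement = kr),
    data.table(participant_id = id, visit = "followup", age = 62,
               sex = "female", race = "white", bmi = bmi, womac_total = womac_f,
               cesd = 5, pase = 150, gait_speed = 1.3, fts = 10, falls = 0L,
               kl_left = kl, kl_right = kl, jsw_left = 4, jsw_right = 4,
               knee_replacement = kr)
  )
  clinical <- rbind(mk("A"), mk("B", kr = TRUE), mk("C", kl = NA_integer_),
                    mk("D", bmi = NA_real_), mk("E", womac_f = 25))
  wear_participants <- CJ(participant_id = c("A", "B", "C", "D", "E"),
                          visit = c("baseline", "followup"))
  wear_participants[, n_valid_days := 5L]
  wear_participants[, included := participant_id != "E"]

  res <- apply_exclusions(clinical, wear_participants)
  expect_equal(sort(res$included), "A")
  lg <- res$log
  expect_equal(lg[participant_id == "B"]$reason, "knee_replacement")
  expect_equal(lg[participant_id == "C"]$reason, "missing_radiograph")
  expect_equal(lg[participant_id == "D"]$reason, "missing_covariate")
  expect_equal(lg[participant_id == "E"]$reason, "invalid_accelerometry")
  expect_true(is.na(lg[participant_id == "A"]$reason))
  expect_equal(as.character(res$clinical$group), "stable")

  # carried-forward KL keeps a participant whose follow-up reading is missing
  cf <- mk("F")
  cf[visit == "followup", kl_left := NA_integer_]
  res2 <- apply_exclusions(cf, NULL)
  expect_equal(res2$included, "F")
  expect_equal(res2$clinical$kl_worse_followup, 2)
})
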