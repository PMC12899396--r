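#' Published reference group summaries
#'
#' Group-level summary statistics reported for a 782-participant hip-worn
#' accelerometer sub-study of knee osteoarthritis (659 stable and 123
#' worsening by the MCID rule of a more than 10-point WOMAC increase):
#' per-group means and SDs at
#' baseline and follow-up and of within-person change scores. Units follow
#' the published convention (daily total activity in 10^4 counts/day;
#' intensity categories in min/day). These values are inputs for worked
#' examples — e.g. feeding group means into [percent_change()] — not
#' outputs of this package.
#'
#' @return `data.table` with columns `variable`, `group`, `n`,
#'   `baseline_mean`, `baseline_sd`, `followup_mean`, `followup_sd`,
#'   `change_mean`, `change_sd`.
#' @export
koa_reference_summaries <- function() {
  rbindlist(list(
    ref_row("womac_total", 12.1, 15.5, 10.2, 12.7, -1.9, 8.1,
            10.8, 10.9, 30.4, 13.1, 19.6, 9.2),
    ref_row("cesd", 6.1, 7.1, 6.0, 6.4, -0.2, 5.9,
            6.8, 7.4, 7.1, 7.7, 0.3, 6.4),
    ref_row("pase", 159.2, 80.5, 160.9, 79.6, 1.7, 74.0,
            161.9, 83.8, 160.6, 84.5, -1.4, 65.0),
    ref_row("gait_speed", 1.34, 0.20, 1.33, 0.20, -0.015, 0.11,
            1.33, 0.21, 1.26, 0.22, -0.067, 0.14),
    ref_row("fts", 10.50, 3.95, 10.42, 3.93, -0.034, 1.99,
            11.53, 5.00, 12.01, 5.12, 0.563, 2.09),
    ref_row("jsw_worse", 3.79, 1.44, 3.74, 1.50, -0.047, 0.43,
            3.70, 1.50, 3.57, 1.64, -0.132, 0.46),
    ref_row("daily_total_activity", 22.1, 10.6, 19.8, 10.5, -2.2, 7.6,
            22.1, 11.3, 18.1, 9.5, -4.0, 7.6),
    ref_row("sed_min", 581.3, 82.0, 594.9, 81.5, 13.7, 73.7,
            572.0, 80.7, 584.5, 91.3, 12.5, 67.8),
    ref_row("lpa_min", 277.0, 74.9, 254.4, 77.5, -22.6, 62.6,
            283.9, 80.5, 254.8, 74.5, -29.1, 56.9),
    ref_row("mvpa_min", 19.8, 19.4, 17.3, 18.3, -2.5, 14.3,
            19.0, 20.0, 13.6, 16.0, -5.4, 14.9)
  ))
}

ref_row <- function(variable, sb, sbs, sf, sfs, sc, scs,
                    wb, wbs, wf, wfs, wc, wcs) {
  data.table(
    variable = variable,
    group = c("stable", "worsening"),
    n = c(659L, 123L),
    baseline_mean = c(sb, wb), baseline_sd = c(sbs, wbs),
    followup_mean = c(sf, wf), followup_sd = c(sfs, wfs),
    change_mean = c(sc, wc), change_sd = c(scs, wcs)
  )
}

#' Published baseline radiographic contingency
#'
#' Counts of participants with radiographic knee OA (worse-knee KL grade
#' >= 2) versus below, by group, at baseline: a 2x2 table for the
#' chi-square worked example.
#'
#' @return 2x2 integer matrix (rows stable/worsening, columns ge2/lt2).
#' @export
koa_reference_kl_table <- function() {
  matrix(c(490L, 101L, 169L, 22L), nrow = 2L,
         dimnames = list(group = c("stable", "worsening"),
                         kl = c("ge2", "lt2")))
}

#' Run the full accelerometer analysis pipeline on a cohort
#'
#' Convenience orchestrator: wear validation, day and visit intensity
#' summaries, diurnal interval summaries and change scores, clinical
#' exclusions and MCID grouping.
#'
#' @param cohort list with `epochs` and `clinical` (e.g. from
#'   [generate_cohort()]).
#' @param ... passed to [validate_wear()].
#' @return list: `wear`, `days`, `visits`, `intervals`, `changes`,
#'   `exclusions`, `groups` (`data.table` of included participant ids and
#'   group labels).
#' @export
run_pipeline <- function(cohort, ...) {
  wear <- validate_wear(cohort$epochs, ...)
  days <- summarize_days(cohort$epochs, wear)
  visits <- summarize_visits(days, wear)
  intervals <- summarize_intervals(cohort$epochs, wear)
  changes <- interval_change(intervals)
  excl <- apply_exclusions(cohort$clinical, wear$participants)
  groups <- excl$clinical[, .(participant_id, group)]
  list(wear = wear, days = days, visits = visits, intervals = intervals,
       changes = changes, exclusions = excl, groups = groups,
       clinical = cohort$clinical)
}

#' Build the cohort comparison tables
#'
#' Assembles the three report shapes of the analysis: baseline cohort
#' characteristics (`table1`), the Stable-vs-Worsening comparison of
#' clinical and activity outcomes at baseline, follow-up and as change
#' scores with longitudinal percent changes (`table2`), and the diurnal
#' profile (`figure2`: per metric, 3-h bin, visit and group) with per-bin
#' between-group tests (`interval_tests`).
#'
#' @param pipeline result of [run_pipeline()].
#' @param alpha two-sided significance level (default 0.05).
#' @param correct Yates correction for chi-square tests (default `FALSE`).
#' @return list: `table1`, `table2`, `figure2`, `interval_tests`.
#' @export
build_tables <- function(pipeline, alpha = 0.05, correct = FALSE) {
  derived <- pipeline$exclusions$clinical
  groups <- pipeline$groups
  visits <- pipeline$visits[groups, on = "participant_id", nomatch = NULL]
  visits[, total_1e4 := total_counts / 1e4]

  clin <- pipeline$clinical[groups, on = "participant_id", nomatch = NULL]
  clin_wide <- dcast(clin, participant_id + group ~ visit,
                     value.var = c("cesd", "pase", "gait_speed", "fts"))
  cb <- clin[visit == "baseline"]

  # --- table 1: baseline characteristics of the included cohort ----------
  vb <- visits[visit == "baseline"]
  table1 <- data.table(
    variable = c("n", "womac_total", "gait_speed", "fts",
                 "jsw_worse", "kl_ge2_pct",
                 "daily_total_activity_1e4", "sed_min", "lpa_min", "mvpa_min"),
    value = c(nrow(derived),
              mean(derived$womac_baseline),
              mean(cb$gait_speed), mean(cb$fts),
              mean(derived$jsw_worse_baseline, na.rm = TRUE),
              100 * mean(derived$kl_worse_baseline >= 2),
              mean(vb$total_1e4), mean(vb$sed_min), mean(vb$lpa_min),
              mean(vb$mvpa_min))
  )

  # --- table 2: three comparisons per variable ---------------------------
  act_wide <- dcast(visits, participant_id + group ~ visit,
                    value.var = c("total_1e4", "total_steps",
                                  "sed_min", "lpa_min", "mvpa_min"))
  act_vars <- c(daily_total_activity = "total_1e4",
                daily_total_steps = "total_steps",
                sed_min = "sed_min", lpa_min = "lpa_min",
                mvpa_min = "mvpa_min")

  rows <- list()
  add_cont <- function(name, base, fup, grp) {
    chg <- fup - base
    s <- grp == "stable"; w <- grp == "worsening"
    out <- list(
      baseline = compare_variable(base[s], base[w], name, "continuous",
                                  alpha = alpha),
      followup = compare_variable(fup[s], fup[w], name, "continuous",
                                  alpha = alpha),
      change = compare_variable(chg[s], chg[w], name, "continuous",
                                alpha = alpha)
    )
    for (phase in names(out)) set(out[[phase]], j = "phase", value = phase)
    chg_row <- out$change
    mb_s <- mean(base[s], na.rm = TRUE)
    mb_w <- mean(base[w], na.rm = TRUE)
    chg_row[, pct_change_stable :=
              if (is.finite(mb_s) && mb_s > 0)
                percent_change(mb_s, mean_stable) else NA_real_]
    chg_row[, pct_change_worsening :=
              if (is.finite(mb_w) && mb_w > 0)
                percent_change(mb_w, mean_worsening) else NA_real_]
    rows[[length(rows) + 1L]] <<- rbindlist(out, fill = TRUE)
  }

  for (nm in names(act_vars)) {
    v <- act_vars[[nm]]
    add_cont(nm, act_wide[[paste0(v, "_baseline")]],
             act_wide[[paste0(v, "_followup")]], act_wide$group)
  }
  add_cont("womac_total", derived$womac_baseline, derived$womac_followup,
           derived$group)
  add_cont("jsw_worse", derived$jsw_worse_baseline,
           derived$jsw_worse_followup, derived$group)
  for (nm in c("cesd", "pase", "gait_speed", "fts")) {
    add_cont(nm, clin_wide[[paste0(nm, "_baseline")]],
             clin_wide[[paste0(nm, "_followup")]], clin_wide$group)
  }

  # categorical: radiographic OA (worse-knee KL >= 2) at each visit
  for (phase in c("baseline", "followup")) {
    kl <- derived[[paste0("kl_worse_", phase)]]
    r <- compare_variable(factor(kl[derived$group == "stable"] >= 2,
                                 levels = c(FALSE, TRUE)),
                          factor(kl[derived$group == "worsening"] >= 2,
                                 levels = c(FALSE, TRUE)),
                          "kl_ge2", "categorical", alpha = alpha,
                          correct = correct)
    set(r, j = "phase", value = phase)
    rows[[length(rows) + 1L]] <- r
  }
  table2 <- rbindlist(rows, fill = TRUE)
  setcolorder(table2, c("variable", "phase"))

  # --- figure 2 shape and per-bin tests ----------------------------------
  ints <- pipeline$intervals[groups, on = "participant_id", nomatch = NULL]
  metrics <- c("total_counts", "sed_min", "lpa_min", "mvpa_min")
  figure2 <- ints[, lapply(.SD, mean), by = .(group, visit, bin),
                  .SDcols = metrics]
  setorder(figure2, group, visit, bin)

  chg <- pipeline$changes[groups, on = "participant_id", nomatch = NULL]
  test_rows <- list()
  for (m in metrics) {
    for (b in 0:7) {
      sub_b <- ints[bin == b & visit == "baseline"]
      sub_f <- ints[bin == b & visit == "followup"]
      sub_c <- chg[bin == b]
      mk <- function(dt, col, phase) {
        r <- compare_variable(dt[group == "stable"][[col]],
                              dt[group == "worsening"][[col]],
                              m, "continuous", alpha = alpha)
        set(r, j = "phase", value = phase)
        set(r, j = "bin", value = b)
        r
      }
      test_rows[[length(test_rows) + 1L]] <- rbindlist(list(
        mk(sub_b, m, "baseline"),
        mk(sub_f, m, "followup"),
        mk(sub_c, paste0(m, "_change"), "change")
      ), fill = TRUE)
    }
  }
  interval_tests <- rbindlist(test_rows, fill = TRUE)
  interval_tests[, daytime := bin %in% daytime_bins()]
  setcolorder(interval_tests, c("variable", "bin", "phase", "daytime"))

  list(table1 = table1, table2 = table2, figure2 = figure2,
       interval_tests = interval_tests)
}
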