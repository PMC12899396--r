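# koawear

Accelerometer-based analysis of knee-osteoarthritis (KOA) symptom
worsening in longitudinal cohorts.

Adults with or at risk of KOA wear a hip-mounted accelerometer for a week
at two visits two years apart; the device records vertical-axis activity
counts and steps in 1-minute epochs. Patients whose WOMAC total score
(0-96, higher = worse) rises by more than 10 points — the minimal
clinically important difference (MCID) — between visits are *Worsening*;
everyone else is *Stable*. `koawear` implements the complete analysis
chain that asks how much activity the two groups lose, and **when during
the day** the loss is concentrated:

* **Non-wear detection** — intervals of ≥ 90 consecutive zero-count
  minutes, allowing up to 2 interior minutes with counts in (0, 100),
  detected by a greedy maximal scan (Rcpp); days with ≥ 10 h of wear are
  valid; participant-visits with 4-7 valid days are included.
* **Intensity classification** — Freedson cut-points: SED 0-99,
  LPA 100-1951, MVPA ≥ 1952 counts/min; daily totals averaged over valid
  days.
* **Diurnal segmentation** — eight half-open 3-h clock bins
  `[3k, 3k+3)`; primary analyses use the four daytime bins 09:00-21:00;
  per-bin change scores and group percent changes as the ratio of group
  means, `100 · mean(Δ) / mean(baseline)`.
* **Clinical derivations** — exclusion cascade (knee replacement,
  missing radiographs, missing covariates, invalid accelerometry),
  worse-knee selection (higher KL grade, then smaller medial minimum
  JSW), adjacent-visit JSW imputation, KL carry-forward, MCID grouping.
* **Group comparison battery** — Shapiro-Wilk-gated Welch t /
  Mann-Whitney tests, chi-square for categorical variables, two-sided
  α = 0.05; builders for baseline-characteristics, outcome-comparison and
  diurnal-profile tables.
* **Synthetic cohort generator** — a seeded, fully tested generator that
  emulates the two-visit protocol (diurnal count profiles, overnight and
  sporadic daytime non-wear, bout-like MVPA, group-specific late-day
  activity declines, WOMAC changes consistent with the MCID rule), so the
  whole pipeline is testable without access-restricted cohort data.

See `vignettes/koawear-methods.Rmd` for the model, parameter and design
details.

## Worked example

```r
library(koawear)
library(data.table)

spec <- cohort_spec(n_participants = 60, seed = 42)
cohort <- generate_cohort(spec)
pipeline <- run_pipeline(cohort)

pipeline$wear$participants[1:3]
#>    participant_id    visit n_valid_days included
#> 1:         P00001 baseline            7     TRUE
#> 2:         P00001 followup            7     TRUE
#> 3:         P00002 baseline            7     TRUE

mean(pipeline$groups$group == "worsening")
#> [1] 0.122807

est <- interval_pct_change(pipeline$changes, pipeline$groups)
est[bin %in% c(5, 6)]
#>        group   bin     n mean_baseline mean_change pct_change
#> 1:    stable     5    50      44243.86   -2916.781  -6.592509
#> 2:    stable     6    50      28801.70   -1771.267  -6.149872
#> 3: worsening     5     7      47687.10   -8849.143 -18.556680
#> 4: worsening     6     7      27515.61   -5732.303 -20.832910
```

Seven of the 57 included participants worsened (12.3%; the generator's
expected prevalence is 16%). In the late-afternoon (bin 5, 15:00-18:00)
and evening (bin 6, 18:00-21:00) clock bins the worsening group's total
activity counts fell by 19-21% against 6-7% in the stable group —
recovering the generator's injected decline factors (0.79 vs 0.94 in
those bins). The comparison battery then reports, per variable and phase,
the group means, the gated test and its p-value:

```r
build_tables(pipeline)$table2[variable == "mvpa_min" & phase == "change"]
#>    variable  phase n_stable n_worsening mean_stable ... test    p_value significant
#> 1: mvpa_min change       50           7   -1.872381 ... t_test 0.03402098      TRUE
```

i.e. on this synthetic cohort the worsening group loses significantly
more MVPA minutes per day than the stable group (-3.2 vs -1.9 min/day,
Welch t, p = 0.034).

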