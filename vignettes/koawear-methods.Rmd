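---
title: "Accelerometer processing and group comparison methods in koawear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerometer processing and group comparison methods in koawear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(koawear)
library(data.table)
```

## The scientific problem

Knee osteoarthritis (KOA) symptoms fluctuate over years, and roughly one in
six patients experiences clinically meaningful worsening over a two-year
interval. Hip-worn accelerometers record minute-by-minute activity counts
continuously over a week, which makes it possible to ask not only *how
much* activity a patient loses as symptoms worsen, but *when during the
day* that loss is concentrated.

`koawear` implements the complete analysis chain for this question in a
longitudinal two-visit design:

1. **Wear validation** — detect non-wear from sustained zero-count runs,
   keep days with at least 10 h of wear, keep participant-visits with 4-7
   valid days.
2. **Intensity summarization** — classify each worn minute by Freedson
   count cut-points (SED 0-99, LPA 100-1951, MVPA >= 1952 counts/min) and
   average daily totals over valid days.
3. **Diurnal segmentation** — tile the day into eight 3-h clock bins and
   summarize each, with primary attention on the four daytime bins
   (09:00-21:00) where non-wear is minimal.
4. **Clinical derivations** — exclusion cascade, worse-knee selection,
   adjacent-visit JSW imputation, KL carry-forward, and Stable/Worsening
   classification by the WOMAC minimal clinically important difference
   (an increase of more than 10 points on the 0-96 total score).
5. **Group comparison** — Shapiro-Wilk-gated Welch t / Mann-Whitney tests
   and chi-square tests at baseline, follow-up, and on within-person
   change scores, including per-bin change comparisons.

Because the source cohort data are access-restricted, the package ships a
seeded synthetic cohort generator with the same data structure, so every
stage is exercised end to end by tests with no download.

## The non-wear rule

Non-wear is an interval of at least 90 consecutive minutes of zero counts,
allowing up to 2 interior minutes with counts strictly below
100 counts/min. Several readings of that rule are possible; the package
fixes these choices:

* **Allowance semantics.** "Up to 2 min" is read as at most two
  interruption epochs *in total* per interval, not per sub-window, and the
  interruptions need not be consecutive. The Choi-style refinement with
  flanking-window checks is a different algorithm and is deliberately not
  implemented; the window length, allowance count and threshold are
  arguments, so a stricter variant can be configured.
* **Interior interruptions only.** Intervals start and end on zero-count
  epochs. Otherwise trailing sub-threshold activity could inflate
  intervals arbitrarily.
* **Greedy left-to-right maximality.** From each candidate start the scan
  takes the longest admissible extension; accepted intervals are skipped;
  a failed start advances by a single epoch because a later start can
  yield a longer window by *not* spending allowance on an early
  interruption. This makes the output unique and order-independent.
* **Calendar-day boundaries.** Days are clock-anchored (the diurnal bins
  are too), so a physical removal spanning midnight is split at 00:00 and
  each part must independently satisfy the 90-min rule.
* Epochs with counts in (0, 100) outside any qualifying window are wear
  time: the rule defines non-wear only.

The test suite checks the scanner against two independently derived
oracles (an \\(O(n^2)\\) prefix-sum enumeration of all admissible windows,
and an \\(O(n)\\) combinatorial enumeration over interruption subsets) on
tens of thousands of randomized sequences.

```{r nonwear-example}
day <- c(rep(500L, 5), rep(0L, 45), 50L, rep(0L, 45), rep(500L, 5))
detect_nonwear(day)
```

## Cut-points and accounting identities

The literal cut-point text (LPA up to 1951, MVPA above 1952) leaves the
single count value 1952 unassigned; `classify_epoch()` assigns 1952 to
MVPA, matching the >= 1952 convention of the Freedson thresholds, so that
the categories partition the non-negative integers. Two identities are
enforced by construction and asserted across every synthetic participant
in the tests:

* per day, `sed_min + lpa_min + mvpa_min == wear_min`;
* per 3-h bin, intensity minutes plus non-wear minutes tile the 180
  bin-minutes, and bin totals aggregate exactly to day totals.

Non-wear percentage per bin is computed against the full 180 bin-minutes
(not conditionally on wear), which is the reading under which the
percentages are interpretable as a share of the clock window.

## Percent change conventions

Group-level percent change is the **ratio of group means**:
\\(100 \\cdot \\overline{\\Delta} / \\bar{x}_{baseline}\\). This is the
convention under which longitudinal percentages reconcile exactly with
tabulated group means (for example, a worsening-group daily-count decline
of 4.0 on a baseline of 22.1 gives \\(-18.1\\%\\)). Mean-of-ratios
estimates per participant are also available from `interval_change()`,
which flags zero-baseline cells as `NA` rather than reporting silent
zeros. For bins that pool (e.g. 15:00-21:00), changes and baselines are
summed within participant before the ratio of means is taken; per-bin
estimates are exposed alongside so either reading is available.

## Grouping and clinical derivations

* `classify_group()` uses the strict rule `change > 10` for worsening.
  Everything else — including improvements larger than 10 points — is
  stable, because the two groups exhaust the cohort by design. The MCID is
  an argument, so a symmetric-band variant can be configured.
* Worse-knee selection: higher KL; KL tie broken by smaller JSW; double
  tie (or a tie that a missing JSW cannot break) resolved to the right
  knee — a fixed, documented convention so the derivation is
  deterministic.
* JSW imputation averages only *observed* adjacent visits, so an imputed
  value never leaves the convex hull of its neighbours; KL grades carry
  the most recent earlier reading forward (condition stability).
* The exclusion cascade is ordered and logged: knee replacement, then
  missing radiographs, then missing covariates, then invalid
  accelerometry; each participant gets the first applying reason code.

## Statistical battery

Normality is assessed per group with Shapiro-Wilk; a variable is treated
as normal only when both groups pass at 0.05 (the conservative reading —
a pooled test can mask one skewed group). Continuous comparisons use the
Welch unequal-variance t-test (group sizes are very unequal, roughly
84%/16%) or the Mann-Whitney U test; categorical variables use chi-square
without continuity correction by default (`correct = TRUE` is available;
with the published baseline radiographic contingency the uncorrected test
gives p = 0.066 and the corrected one p = 0.085 — both non-significant).
No multiple-testing correction is applied by default, mirroring the
simple group-based design; `stats::p.adjust` can be applied to any table
column by the user. Zero-variance comparisons are flagged as degenerate
and reported with p = 1 rather than an error, so table builders never
produce silent gaps.

Under null synthetic cohorts (no injected group difference) the battery's
empirical rejection rate per daytime-bin change comparison sits inside
the binomial 95% band around 0.05 over 200 replicates; this is asserted
in the test suite.

## The synthetic cohort generator

The generator emulates the structure the pipeline assumes: two visits,
seven recorded days per visit, 1440 one-minute epochs per day.

**Count model.** Worn epochs follow a zero-inflated, right-skewed
mixture. Sedentary epochs are zero with probability 0.45 and otherwise
draw small negative-binomial counts; light-activity epochs draw
`100 + NB(mu = 400)`; per day, 0-3 contiguous bouts of 10-25 min draw
elevated counts (`400 + NB(mu = 2800)`), so MVPA minutes arrive in bouts
rather than isolated epochs and occasionally dip below the MVPA
cut-point, stressing the classification logic. The hourly allocation of
light activity and bout starts follows the diurnal profile (default: low
overnight, morning rise, late-morning plateau near 300 counts/min,
evening decline). The light-activity probability is calibrated so
expected daily LPA minutes match the intensity target; SED minutes then
follow as the wear-time complement. Defaults target 580/278/20
SED/LPA/MVPA min/day — the magnitudes reported for older KOA cohorts —
and land within a few percent of them.

**Non-wear model.** The device is off overnight (22:00-07:00 by default;
the analysis window 09:00-21:00 was chosen in the source design precisely
because non-wear is minimal there) plus sporadic daytime removals
(Poisson rate 0.3/day, gamma-distributed durations with mean 150 min,
emulating water-based activities). True non-wear is recorded literally as
zero counts and flagged in the returned ground truth, which the tests use
to verify that the detector's output is consistent with it.

**Habitual timing.** Removal times and bout times are drawn once per
participant-day and reused at both visits, while all counts are redrawn
fresh per visit. Within-person diurnal timing is highly stable over a
two-year interval (people bathe, swim and exercise at habitual times), so
sharing the schedule is the realistic choice; it also means change scores
reflect changes in activity *level* rather than schedule shuffling.

**Injected declines.** At the follow-up visit every epoch count is
binomially thinned by a group- and clock-bin-specific factor (factors
above 1 add a Poisson top-up), so the expected count scales *exactly* by
the factor — the property that makes parameter-recovery tests sharp.
Default factors concentrate the worsening group's decline in the
late-afternoon and evening bins (0.79 in 15:00-21:00 versus 0.85
elsewhere; stable group 0.94 versus 0.86), emulating the reported
pattern of daily declines near -18%/-10% with late-day declines near
-21%/-6%. Thinning moves borderline epochs across the LPA/MVPA
boundaries, so MVPA minutes decline proportionally more than total
counts — as observed in real cohorts.

**WOMAC model.** Worsening participants draw changes from
`10 + Gamma` (support strictly above the MCID); stable participants from
a normal truncated to (-10, 10). Group labels are therefore functionally
determined by the drawn changes, and the grouping stage recovers them
exactly — asserted cohort-wide in the tests.

**What the generator does not emulate.** Raw 30-Hz accelerations, bout
structure of sedentary behaviour, weekday/weekend differences (pooled in
the source protocol), device anomalies, seasonal effects, and any
correlation between activity decline and the WOMAC change beyond the
shared group label. Passing tests demonstrate that the *pipeline*
computes the intended quantities on data with the assumed structure; they
are not evidence about real cohorts.

## Problem sizes and numerical choices

The test suite uses cohorts of 200 participants (accounting identities),
500 participants (parameter recovery, the size at which the recovery
tolerance of 3 percentage points is comfortably above the Monte-Carlo
error of the per-bin estimates), and 200 null replicates of 50
participants with 4 recorded days per visit (type-I error; replicates in
which either group has fewer than five included participants are not
testable and are skipped, with at least 170 of 200 required). The
non-wear scanner is checked against the enumeration oracle on 10,000
random sequences of up to 2000 epochs. All seeds are fixed constants in
the test files.

Degenerate inputs are handled explicitly: empty cohorts generate empty
tables; a zero-baseline percent change is `NA`, never 0; zero-variance
comparisons are flagged with p = 1; days with no valid wear never enter
means; and a participant-visit with more than 7 recorded days is an
error, not a silent truncation.

## A worked example

```{r example}
spec <- cohort_spec(n_participants = 60, seed = 42)
cohort <- generate_cohort(spec)
pipeline <- run_pipeline(cohort)

# wear filtering
pipeline$wear$participants[1:3]

# recovered prevalence and late-day decline by group
mean(pipeline$groups$group == "worsening")
est <- interval_pct_change(pipeline$changes, pipeline$groups)
est[bin %in% c(5, 6)]

# full comparison tables
tabs <- build_tables(pipeline)
tabs$table2[variable == "mvpa_min" & phase == "change"]
```

## Known limitations

* The simplified stated non-wear rule is implemented; cohorts processed
  with the full Choi algorithm (flanking-window condition) will classify
  slightly more short zero-runs as non-wear. The parameters are exposed
  for sensitivity analyses.
* Percent changes are descriptive ratios of means; no uncertainty
  intervals are attached to them (the battery's p-values refer to the
  underlying change scores).
* The battery performs unadjusted two-group comparisons by design; no
  mixed-effects or multivariable adjustment is provided.
* Steps are carried through every summary but have no calibrated
  generator target; treat synthetic step counts as plumbing.
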