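#' Assign epochs to 3-hour diurnal bins
#'
#' The 24-hour day is tiled by eight half-open 3-hour clock bins indexed
#' 0-7: bin k covers `[3k, 3k+3)` hours (00:00-03:00 is bin 0, ...,
#' 21:00-24:00 is bin 7). Epochs are assigned by their start time.
#'
#' @param x minute-of-day integers (0-1439), `POSIXct`/`POSIXlt`
#'   timestamps, or `"HH:MM"` strings.
#' @return integer bin indices 0-7.
#' @export
#' @examples
#' assign_bin(c("09:00", "11:59", "12:00", "00:00", "23:59"))
assign_bin <- function(x) {
  minute <- if (inherits(x, "POSIXt")) {
    lt <- as.POSIXlt(x)
    lt$hour * 60L + lt$min
  } else if (is.character(x)) {
    as.integer(substr(x, 1L, 2L)) * 60L + as.integer(substr(x, 4L, 5L))
  } else {
    as.integer(x)
  }
  if (anyNA(minute) || any(minute < 0L | minute > 1439L)) {
    stop("minute-of-day must lie in [0, 1439]")
  }
  minute %/% 180L
}

#' Indices of the daytime analysis bins
#'
#' The four consecutive daytime bins 09:00-12:00 (morning), 12:00-15:00
#' (early afternoon), 15:00-18:00 (late afternoon) and 18:00-21:00
#' (evening), on which primary analyses focus because non-wear is minimal
#' there.
#'
#' @return integer vector `c(3, 4, 5, 6)`.
#' @export
daytime_bins <- function() 3:6

#' Per-bin diurnal activity summaries
#'
#' For every participant-visit and 3-hour clock bin: means over valid days
#' of activity counts, steps and SED/LPA/MVPA minutes, plus the non-wear
#' percentage of bin time (non-wear minutes over the full 180 bin-minutes).
#' Per day-bin, `sed_min + lpa_min + mvpa_min + non-wear minutes = 180`.
#'
#' @param epochs epoch `data.table`.
#' @param wear result of [validate_wear()] on the same table.
#' @param sed_max,mvpa_min intensity cut-points, see [classify_epoch()].
#' @param include_invalid_days keep invalid days in the averages (default
#'   `FALSE`: valid days only, matching the day-level summaries).
#' @return `data.table` per participant-visit-bin: `total_counts`,
#'   `total_steps`, `sed_min`, `lpa_min`, `mvpa_min`, `nonwear_pct`.
#' @export
summarize_intervals <- function(epochs, wear, sed_max = 99L,
                                mvpa_min = 1952L,
                                include_invalid_days = FALSE) {
  worn <- wear$worn
  stopifnot(length(worn) == nrow(epochs))
  cls <- unclass(classify_epoch(epochs$counts, sed_max, mvpa_min))
  dt <- data.table(
    participant_id = epochs$participant_id, visit = epochs$visit,
    date = epochs$date, bin = epochs$minute %/% 180L,
    counts = epochs$counts, steps = epochs$steps, worn = worn, cls = cls
  )
  if (!include_invalid_days) {
    keep <- wear$days[valid == TRUE, .(participant_id, visit, date)]
    dt <- dt[keep, on = c("participant_id", "visit", "date"), nomatch = NULL]
  }
  daybin <- dt[, .(
    total_counts = sum(as.numeric(counts[worn])),
    total_steps = sum(as.numeric(steps[worn])),
    sed_min = sum(worn & cls == 1L),
    lpa_min = sum(worn & cls == 2L),
    mvpa_min = sum(worn & cls == 3L),
    nonwear_min = sum(!worn),
    bin_min = .N
  ), by = .(participant_id, visit, date, bin)]
  out <- daybin[, .(
    total_counts = mean(total_counts),
    total_steps = mean(total_steps),
    sed_min = mean(sed_min),
    lpa_min = mean(lpa_min),
    mvpa_min = mean(mvpa_min),
    nonwear_pct = 100 * mean(nonwear_min / bin_min)
  ), by = .(participant_id, visit, bin)]
  setorder(out, participant_id, visit, bin)
  out[]
}

#' Within-person per-bin change scores
#'
#' Follow-up minus baseline for every diurnal metric, per participant and
#' bin, restricted to participants present at both visits. Per-participant
#' percent change is reported relative to the participant's baseline and is
#' `NA` (flagged, never a silent zero) when the baseline value is zero.
#'
#' @param intervals from [summarize_intervals()], both visits.
#' @param metrics metric columns to difference.
#' @return `data.table` per participant-bin with `<metric>_baseline`,
#'   `<metric>_change` and `<metric>_pct` columns.
#' @export
interval_change <- function(intervals,
                            metrics = c("total_counts", "total_steps",
                                        "sed_min", "lpa_min", "mvpa_min",
                                        "nonwear_pct")) {
  b <- intervals[visit == "baseline"]
  f <- intervals[visit == "followup"]
  m <- merge(b, f, by = c("participant_id", "bin"), suffixes = c("_b", "_f"))
  out <- m[, .(participant_id, bin)]
  for (v in metrics) {
    base <- m[[paste0(v, "_b")]]
    chg <- m[[paste0(v, "_f")]] - base
    out[, (paste0(v, "_baseline")) := base]
    out[, (paste0(v, "_change")) := chg]
    out[, (paste0(v, "_pct")) := fifelse(base > 0, 100 * chg / base, NA_real_)]
  }
  out[]
}

#' Group-level percent change per diurnal bin
#'
#' Percent change computed as the ratio of group means (group mean change
#' over group mean baseline), the convention under which longitudinal
#' percentages reconcile with tabulated group means. Per-participant
#' ratios are available from [interval_change()].
#'
#' @param changes from [interval_change()].
#' @param groups `data.table` with `participant_id` and `group`.
#' @param metric metric name (default `"total_counts"`).
#' @return `data.table` per group-bin: `mean_baseline`, `mean_change`,
#'   `pct_change`.
#' @export
interval_pct_change <- function(changes, groups, metric = "total_counts") {
  bcol <- paste0(metric, "_baseline")
  ccol <- paste0(metric, "_change")
  x <- changes[groups, on = "participant_id", nomatch = NULL]
  out <- x[, .(
    n = .N,
    mean_baseline = mean(.SD[[1L]]),
    mean_change = mean(.SD[[2L]])
  ), by = .(group, bin), .SDcols = c(bcol, ccol)]
  out[, pct_change := fifelse(mean_baseline > 0,
                              100 * mean_change / mean_baseline, NA_real_)]
  setorder(out, group, bin)
  out[]
}
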