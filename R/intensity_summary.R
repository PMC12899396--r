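#' Classify epoch counts into intensity categories
#'
#' Freedson count cut-points for minute epochs in older adults: sedentary
#' (SED) 0-99 counts/min, light physical activity (LPA) 100-1951, and
#' moderate-to-vigorous physical activity (MVPA) at or above 1952. The
#' `mvpa_min` boundary is inclusive so the three categories partition the
#' non-negative integers.
#'
#' @param counts non-negative integer counts/min (vectorised).
#' @param sed_max highest SED count (default 99).
#' @param mvpa_min lowest MVPA count (default 1952).
#' @return factor with levels `SED`, `LPA`, `MVPA`.
#' @export
#' @examples
#' classify_epoch(c(0, 99, 100, 1951, 1952, 5000))
classify_epoch <- function(counts, sed_max = 99L, mvpa_min = 1952L) {
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing")
  }
  factor(
    ifelse(counts <= sed_max, "SED", ifelse(counts < mvpa_min, "LPA", "MVPA")),
    levels = c("SED", "LPA", "MVPA")
  )
}

#' Summarize one day of worn epochs
#'
#' Totals counts and steps and tallies SED/LPA/MVPA minutes over worn
#' epochs only; non-worn epochs contribute nothing.
#'
#' @param counts,steps one day's epoch vectors.
#' @param worn logical wear mask from [wear_mask()]; same length.
#' @inheritParams classify_epoch
#' @return one-row `data.table`: `wear_min`, `total_counts`, `total_steps`,
#'   `sed_min`, `lpa_min`, `mvpa_min`. Always satisfies
#'   `sed_min + lpa_min + mvpa_min == wear_min`.
#' @export
summarize_day <- function(counts, steps = rep(0L, length(counts)), worn,
                          sed_max = 99L, mvpa_min = 1952L) {
  if (length(worn) != length(counts) || length(steps) != length(counts)) {
    stop("`counts`, `steps` and `worn` must have equal length")
  }
  wc <- counts[worn]
  cls <- classify_epoch(wc, sed_max, mvpa_min)
  data.table(
    wear_min = sum(worn),
    total_counts = sum(as.numeric(wc)),
    total_steps = sum(as.numeric(steps[worn])),
    sed_min = sum(cls == "SED"),
    lpa_min = sum(cls == "LPA"),
    mvpa_min = sum(cls == "MVPA")
  )
}

#' Per-day activity summaries for a whole epoch table
#'
#' Day-level totals of counts, steps and intensity minutes over worn
#' epochs, joined with the valid-day flag.
#'
#' @param epochs epoch `data.table`.
#' @param wear result of [validate_wear()] on the same table.
#' @inheritParams classify_epoch
#' @return `data.table` per participant-visit-date with `wear_min`,
#'   `total_counts`, `total_steps`, `sed_min`, `lpa_min`, `mvpa_min`,
#'   `valid`.
#' @export
summarize_days <- function(epochs, wear, sed_max = 99L, mvpa_min = 1952L) {
  worn <- wear$worn
  stopifnot(length(worn) == nrow(epochs))
  cls <- unclass(classify_epoch(epochs$counts, sed_max, mvpa_min))
  dt <- data.table(
    participant_id = epochs$participant_id, visit = epochs$visit,
    date = epochs$date, counts = epochs$counts, steps = epochs$steps,
    worn = worn, cls = cls
  )
  out <- dt[, .(
    wear_min = sum(worn),
    total_counts = sum(as.numeric(counts[worn])),
    total_steps = sum(as.numeric(steps[worn])),
    sed_min = sum(worn & cls == 1L),
    lpa_min = sum(worn & cls == 2L),
    mvpa_min = sum(worn & cls == 3L)
  ), by = .(participant_id, visit, date)]
  out[wear$days, valid := i.valid, on = c("participant_id", "visit", "date")]
  out[]
}

#' Per-visit activity summary (means over valid days)
#'
#' Unweighted arithmetic means of the day-level metrics over valid days
#' only, restricted to included participant-visits (4-7 valid days).
#'
#' @param day_summaries from [summarize_days()].
#' @param wear result of [validate_wear()]; participant-visits not included
#'   by the valid-participant rule are dropped.
#' @return `data.table` per participant-visit: `n_valid_days` and means
#'   `wear_min`, `total_counts`, `total_steps`, `sed_min`, `lpa_min`,
#'   `mvpa_min`.
#' @export
summarize_visits <- function(day_summaries, wear = NULL) {
  ds <- day_summaries[valid == TRUE]
  out <- ds[, .(
    n_valid_days = .N,
    wear_min = mean(wear_min),
    total_counts = mean(total_counts),
    total_steps = mean(total_steps),
    sed_min = mean(sed_min),
    lpa_min = mean(lpa_min),
    mvpa_min = mean(mvpa_min)
  ), by = .(participant_id, visit)]
  if (!is.null(wear)) {
    keep <- wear$participants[included == TRUE, .(participant_id, visit)]
    out <- out[keep, on = c("participant_id", "visit"), nomatch = NULL]
  }
  out[]
}
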