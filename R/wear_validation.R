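#' Detect non-wear intervals in one day of minute epochs
#'
#' A non-wear interval is a run of at least `min_window_min` consecutive
#' minute epochs recorded with zero counts, allowing up to
#' `allowance_count` interior epochs with counts strictly between zero and
#' `allowance_threshold` counts/min. Intervals start and end on zero-count
#' epochs; an epoch at or above the threshold always breaks the window.
#' Detection is a greedy left-to-right scan taking the longest admissible
#' extension from each candidate start, which makes the output unique;
#' accepted intervals are disjoint and maximal.
#'
#' @param counts integer vector of one calendar day's counts/min (any
#'   length >= 1; a full day has 1440).
#' @param min_window_min minimum interval length in minutes (default 90).
#' @param allowance_count maximum number of interior interruption epochs
#'   (default 2).
#' @param allowance_threshold counts/min; interruption epochs must be
#'   strictly below this (default 100).
#' @return `data.table` with one row per interval: `start` (1-based,
#'   inclusive), `end` (exclusive), `length` (minutes, `end - start`).
#' @export
#' @examples
#' day <- c(rep(500L, 5), rep(0L, 45), 50L, rep(0L, 45), rep(500L, 5))
#' detect_nonwear(day) # one 91-min interval with one allowance epoch
detect_nonwear <- function(counts, min_window_min = 90L,
                           allowance_count = 2L,
                           allowance_threshold = 100L) {
  counts <- as.integer(counts)
  if (length(counts) < 1L) stop("`counts` must contain at least one epoch")
  if (anyNA(counts) || any(counts < 0L)) {
    stop("counts must be non-negative and non-missing")
  }
  res <- nonwear_scan_cpp(counts, 0L, as.integer(min_window_min),
                          as.integer(allowance_count),
                          as.integer(allowance_threshold))
  data.table(start = res$start + 1L, end = res$end + 1L,
             length = res$end - res$start)
}

#' Per-epoch wear mask for one day
#'
#' `TRUE` for worn epochs, i.e. epochs not covered by any detected
#' non-wear interval.
#'
#' @inheritParams detect_nonwear
#' @return logical vector the length of `counts`.
#' @export
wear_mask <- function(counts, min_window_min = 90L, allowance_count = 2L,
                      allowance_threshold = 100L) {
  counts <- as.integer(counts)
  if (length(counts) < 1L) stop("`counts` must contain at least one epoch")
  if (anyNA(counts) || any(counts < 0L)) {
    stop("counts must be non-negative and non-missing")
  }
  nonwear_scan_cpp(counts, 0L, as.integer(min_window_min),
                   as.integer(allowance_count),
                   as.integer(allowance_threshold))$worn
}

#' Wear minutes in one day
#'
#' Number of epochs not covered by any non-wear interval.
#'
#' @param counts one day's counts/min.
#' @param intervals intervals from [detect_nonwear()] on the same day;
#'   detected afresh when omitted.
#' @inheritParams detect_nonwear
#' @return integer minutes.
#' @export
wear_minutes <- function(counts, intervals = NULL, min_window_min = 90L,
                         allowance_count = 2L, allowance_threshold = 100L) {
  if (is.null(intervals)) {
    intervals <- detect_nonwear(counts, min_window_min, allowance_count,
                                allowance_threshold)
  }
  length(counts) - sum(intervals$length)
}

#' Wear validation for a whole epoch table
#'
#' Runs non-wear detection on every participant-visit calendar day of an
#' epoch table and applies the valid-day (>= `min_wear_min` wear minutes)
#' and valid-participant (`min_valid_days`-`max_valid_days` valid days per
#' visit) filters.
#'
#' @param epochs epoch `data.table` (columns `participant_id`, `visit`,
#'   `date`, `minute`, `counts`), sorted by those columns. Each day must be
#'   a complete, gap-free block of consecutive minutes.
#' @param min_wear_min minimum wear minutes for a valid day (default 600,
#'   i.e. 10 h).
#' @param min_valid_days,max_valid_days valid-day range for an included
#'   participant-visit (default 4-7). More than `max_valid_days` *recorded*
#'   days in one visit is an error.
#' @inheritParams detect_nonwear
#' @return list with
#'   \describe{
#'     \item{worn}{logical vector aligned with `epochs` rows.}
#'     \item{days}{`data.table` per participant-visit-date: `n_epochs`,
#'       `wear_min`, `valid`.}
#'     \item{participants}{`data.table` per participant-visit:
#'       `n_valid_days`, `included`.}
#'   }
#' @export
validate_wear <- function(epochs, min_window_min = 90L, allowance_count = 2L,
                          allowance_threshold = 100L, min_wear_min = 600L,
                          min_valid_days = 4L, max_valid_days = 7L) {
  stopifnot(all(c("participant_id", "visit", "date", "minute", "counts")
                %in% names(epochs)))
  if (nrow(epochs) == 0L) {
    return(list(
      worn = logical(),
      days = data.table(participant_id = character(), visit = character(),
                        date = as.IDate(integer()), n_epochs = integer(),
                        wear_min = integer(), valid = logical()),
      participants = data.table(participant_id = character(),
                                visit = character(), n_valid_days = integer(),
                                included = logical())
    ))
  }
  if (anyNA(epochs$counts) || any(epochs$counts < 0L)) {
    stop("counts must be non-negative and non-missing")
  }
  if (is.unsorted(epochs$minute) &&
      any(epochs[, is.unsorted(minute), by = .(participant_id, visit, date)]$V1)) {
    stop("epochs must be sorted by minute within each day")
  }

  day_id <- rleidv(epochs, cols = c("participant_id", "visit", "date"))
  block_start <- c(0L, which(diff(day_id) != 0L))
  res <- nonwear_scan_cpp(epochs$counts, block_start,
                          as.integer(min_window_min),
                          as.integer(allowance_count),
                          as.integer(allowance_threshold))
  worn <- res$worn

  days <- epochs[, .(n_epochs = .N), by = .(participant_id, visit, date)]
  days[, wear_min := data.table(d = day_id, w = worn)[, sum(w), by = d]$V1]
  days[, valid := wear_min >= min_wear_min]

  participants <- days[, .(n_days = .N, n_valid_days = sum(valid)),
                       by = .(participant_id, visit)]
  if (any(participants$n_days > max_valid_days)) {
    bad <- participants[participants$n_days > max_valid_days]
    stop(sprintf("more than %d recorded days for %s (%s)", max_valid_days,
                 bad$participant_id[1L], bad$visit[1L]))
  }
  participants[, included := n_valid_days >= min_valid_days &
                 n_valid_days <= max_valid_days]
  participants[, n_days := NULL]

  list(worn = worn, days = days, participants = participants)
}

#' Valid-day records for one participant-visit series
#'
#' One record per calendar day with wear minutes and the >= 10 h validity
#' flag.
#'
#' @param series epoch `data.table` for one participant-visit (columns
#'   `date`, `minute`, `counts`).
#' @inheritParams validate_wear
#' @return `data.table` per date: `wear_min`, `valid`.
#' @export
valid_days <- function(series, min_window_min = 90L, allowance_count = 2L,
                       allowance_threshold = 100L, min_wear_min = 600L) {
  stopifnot(all(c("date", "minute", "counts") %in% names(series)))
  if (nrow(series) == 0L) {
    return(data.table(date = as.IDate(integer()), wear_min = integer(),
                      valid = logical()))
  }
  series[, {
    m <- wear_mask(counts, min_window_min, allowance_count,
                   allowance_threshold)
    .(wear_min = sum(m))
  }, by = date][, valid := wear_min >= min_wear_min][]
}

#' Valid-participant decision for one visit
#'
#' A participant-visit is included when it has 4-7 valid days.
#'
#' @param day_validity `data.table` from [valid_days()] (or any table with
#'   a logical `valid` column, one row per recorded day).
#' @param min_valid_days,max_valid_days inclusion range (default 4-7).
#' @return list with `included` (logical) and `n_valid_days`.
#' @export
valid_participant <- function(day_validity, min_valid_days = 4L,
                              max_valid_days = 7L) {
  if (nrow(day_validity) > max_valid_days) {
    stop(sprintf("more than %d recorded days in one visit", max_valid_days))
  }
  nv <- sum(day_validity$valid)
  list(included = nv >= min_valid_days && nv <= max_valid_days,
       n_valid_days = nv)
}

#' Wear report
#'
#' Flat per-day wear report (participant, visit, date, wear minutes, valid
#' flag), suitable for export with [data.table::fwrite()].
#'
#' @param wear result of [validate_wear()].
#' @return `data.table`.
#' @export
wear_report <- function(wear) {
  wear$days[, .(participant_id, visit, date, wear_min, valid)]
}
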