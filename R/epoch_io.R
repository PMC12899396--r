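#' Read and write minute-epoch CSV files
#'
#' The epoch interchange format has one row per minute epoch and columns
#' `participant_id`, `visit`, `timestamp` (ISO-8601 at minute resolution),
#' `axis1_counts` and `steps`, sorted by participant, visit, timestamp.
#' `write_epoch_csv()` and `read_epoch_csv()` round-trip the internal epoch
#' table losslessly.
#'
#' @param epochs epoch `data.table` as produced by [generate_cohort()]
#'   (columns `participant_id`, `visit`, `date`, `minute`, `counts`,
#'   `steps`).
#' @param path file path.
#' @return `write_epoch_csv()` returns `path` invisibly; `read_epoch_csv()`
#'   returns the epoch `data.table`.
#' @export
write_epoch_csv <- function(epochs, path) {
  stopifnot(all(c("participant_id", "visit", "date", "minute",
                  "counts", "steps") %in% names(epochs)))
  out <- data.table(
    participant_id = epochs$participant_id,
    visit = epochs$visit,
    timestamp = sprintf("%sT%02d:%02d:00", as.character(epochs$date),
                        epochs$minute %/% 60L, epochs$minute %% 60L),
    axis1_counts = epochs$counts,
    steps = epochs$steps
  )
  setorder(out, participant_id, visit, timestamp)
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
read_epoch_csv <- function(path) {
  raw <- fread(path, colClasses = list(
    character = c("participant_id", "visit", "timestamp"),
    integer = c("axis1_counts", "steps")
  ))
  if (nrow(raw) == 0L) {
    return(data.table(participant_id = character(), visit = character(),
                      date = as.IDate(integer()), minute = integer(),
                      counts = integer(), steps = integer()))
  }
  out <- data.table(
    participant_id = raw$participant_id,
    visit = raw$visit,
    date = as.IDate(substr(raw$timestamp, 1L, 10L)),
    minute = as.integer(substr(raw$timestamp, 12L, 13L)) * 60L +
      as.integer(substr(raw$timestamp, 15L, 16L)),
    counts = raw$axis1_counts,
    steps = raw$steps
  )
  setorder(out, participant_id, visit, date, minute)
  out[]
}

#' Read and write the participant-visit clinical CSV
#'
#' One row per participant-visit with demographics, patient-reported and
#' performance outcomes, per-knee radiographic readings and the
#' knee-replacement flag.
#'
#' @param clinical clinical `data.table` as produced by [generate_cohort()].
#' @param path file path.
#' @export
write_clinical_csv <- function(clinical, path) {
  fwrite(clinical, path)
  invisible(path)
}

#' @rdname write_clinical_csv
#' @export
read_clinical_csv <- function(path) {
  x <- fread(path)
  setkey(x, participant_id, visit)
  x[]
}
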