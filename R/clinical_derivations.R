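#' Classify participants by the WOMAC MCID rule
#'
#' A participant is `worsening` when the WOMAC total score increases by
#' strictly more than `mcid` points between baseline and follow-up, and
#' `stable` otherwise (including large improvements; the two labels
#' exhaust the cohort). A change of exactly `mcid` is stable.
#'
#' @param womac_baseline,womac_followup WOMAC total scores (0-96),
#'   vectorised; missing values are an error.
#' @param mcid minimal clinically important difference (default 10).
#' @return factor with levels `stable`, `worsening`.
#' @export
#' @examples
#' classify_group(c(10.8, 12, 30), c(30.4, 10.1, 40.1))
classify_group <- function(womac_baseline, womac_followup, mcid = 10) {
  if (anyNA(womac_baseline) || anyNA(womac_followup)) {
    stop("WOMAC scores must be present at both visits")
  }
  factor(ifelse(womac_followup - womac_baseline > mcid, "worsening", "stable"),
         levels = c("stable", "worsening"))
}

#' Select the worse knee
#'
#' The worse side is the knee with the higher KL grade; on a KL tie, the
#' knee with the smaller medial minimum JSW; on a double tie (or when JSW
#' cannot break the tie), the right knee by convention.
#'
#' @param kl_left,kl_right KL grades 0-4 (after imputation; both must be
#'   present).
#' @param jsw_left,jsw_right medial minimum JSW in mm (may be missing; a
#'   missing JSW cannot break a KL tie).
#' @return character vector of `"left"` / `"right"`.
#' @export
#' @examples
#' select_worse_knee(3, 2, 3.5, 4.0) # left: higher KL
#' select_worse_knee(2, 2, 3.5, 4.0) # left: smaller JSW
#' select_worse_knee(2, 2, 4.0, 4.0) # right: tie-break
select_worse_knee <- function(kl_left, kl_right, jsw_left = NA_real_,
                              jsw_right = NA_real_) {
  if (anyNA(kl_left) || anyNA(kl_right)) {
    stop("both knees' KL grades must be present (impute first)")
  }
  n <- length(kl_left)
  jsw_left <- rep_len(jsw_left, n)
  jsw_right <- rep_len(jsw_right, n)
  side <- rep("right", n)
  side[kl_left > kl_right] <- "left"
  tie <- kl_left == kl_right
  jsw_breaks <- tie & !is.na(jsw_left) & !is.na(jsw_right) &
    jsw_left < jsw_right
  side[jsw_breaks] <- "left"
  side
}

#' Impute missing JSW from adjacent visits
#'
#' Each missing value in a visit-ordered JSW series is replaced by the mean
#' of the observed values at the immediately adjacent visits (one or two of
#' them); it stays missing when neither neighbour was observed. Imputation
#' uses the original observations only, so an imputed value never leaves
#' the convex hull of its observed neighbours.
#'
#' @param jsw numeric vector ordered by visit; `NA` for missing.
#' @return numeric vector with adjacent-mean imputations applied.
#' @export
#' @examples
#' impute_jsw(c(3.8, NA, 3.6)) # middle becomes 3.7
impute_jsw <- function(jsw) {
  jsw <- as.numeric(jsw)
  n <- length(jsw)
  out <- jsw
  for (i in which(is.na(jsw))) {
    adj <- c(if (i > 1L) jsw[i - 1L], if (i < n) jsw[i + 1L])
    adj <- adj[!is.na(adj)]
    if (length(adj)) out[i] <- mean(adj)
  }
  out
}

#' Carry KL grades forward
#'
#' Each missing KL grade in a visit-ordered series is replaced by the most
#' recent earlier observed grade (assuming condition stability); it stays
#' missing when no earlier visit was observed.
#'
#' @param kl integer vector of KL grades ordered by visit; `NA` for
#'   missing.
#' @return vector with last observations carried forward.
#' @export
#' @examples
#' carry_forward_kl(c(2, NA))      # 2, 2
#' carry_forward_kl(c(1, NA, NA))  # 1, 1, 1
carry_forward_kl <- function(kl) {
  out <- kl
  last <- NA
  for (i in seq_along(kl)) {
    if (is.na(out[i])) out[i] <- last else last <- out[i]
  }
  out
}

#' Apply cohort exclusions
#'
#' Applies the exclusion cascade in a fixed, logged order: pre-baseline
#' knee replacement, missing radiographic readings (either knee's KL still
#' missing at baseline after carry-forward), missing baseline covariates
#' (age, sex, BMI) or WOMAC at either visit, and invalid accelerometry
#' (not 4-7 valid wear days at both visits). Each excluded participant is
#' tagged with the first reason that applies.
#'
#' @param clinical participant-visit clinical `data.table` (as from
#'   [generate_cohort()]).
#' @param wear_participants optional per participant-visit inclusion table
#'   (`participants` element of [validate_wear()]); when omitted the
#'   accelerometry criterion is skipped.
#' @return list with
#'   \describe{
#'     \item{included}{character vector of included participant ids.}
#'     \item{log}{`data.table` per participant: `included`, `reason`
#'       (`NA` when included; otherwise `knee_replacement`,
#'       `missing_radiograph`, `missing_covariate` or
#'       `invalid_accelerometry`).}
#'     \item{clinical}{wide derived table for included participants:
#'       worse side, worse-knee KL and JSW per visit, WOMAC change and
#'       group label.}
#'   }
#' @export
apply_exclusions <- function(clinical, wear_participants = NULL) {
  b <- clinical[visit == "baseline"]
  f <- clinical[visit == "followup"]
  setkey(b, participant_id); setkey(f, participant_id)
  stopifnot(identical(b$participant_id, f$participant_id))
  ids <- b$participant_id
  n <- length(ids)
  if (n == 0L) {
    return(list(included = character(),
                log = data.table(participant_id = character(),
                                 included = logical(),
                                 reason = character()),
                clinical = data.table()))
  }
  reason <- rep(NA_character_, n)

  mark <- function(cond, code) {
    reason[is.na(reason) & cond] <<- code
  }
  mark(b$knee_replacement, "knee_replacement")

  # per-knee carry-forward across the two visits, then imputation targets
  kl_l <- t(apply(cbind(b$kl_left, f$kl_left), 1L, carry_forward_kl))
  kl_r <- t(apply(cbind(b$kl_right, f$kl_right), 1L, carry_forward_kl))
  jsw_l <- t(apply(cbind(b$jsw_left, f$jsw_left), 1L, impute_jsw))
  jsw_r <- t(apply(cbind(b$jsw_right, f$jsw_right), 1L, impute_jsw))
  mark(is.na(kl_l[, 1L]) | is.na(kl_r[, 1L]), "missing_radiograph")

  mark(is.na(b$age) | is.na(b$sex) | is.na(b$bmi) |
         is.na(b$womac_total) | is.na(f$womac_total), "missing_covariate")

  if (!is.null(wear_participants)) {
    ok <- wear_participants[, .(acc_ok = all(included) & .N == 2L),
                            by = participant_id]
    acc_ok <- ok$acc_ok[match(ids, ok$participant_id)]
    acc_ok[is.na(acc_ok)] <- FALSE
    mark(!acc_ok, "invalid_accelerometry")
  }

  included <- is.na(reason)
  log <- data.table(participant_id = ids, included = included,
                    reason = reason)

  inc <- which(included)
  worse <- select_worse_knee(kl_l[inc, 1L], kl_r[inc, 1L],
                             jsw_l[inc, 1L], jsw_r[inc, 1L])
  left <- worse == "left"
  derived <- data.table(
    participant_id = ids[inc],
    worse_side = worse,
    kl_worse_baseline = ifelse(left, kl_l[inc, 1L], kl_r[inc, 1L]),
    kl_worse_followup = ifelse(left, kl_l[inc, 2L], kl_r[inc, 2L]),
    jsw_worse_baseline = ifelse(left, jsw_l[inc, 1L], jsw_r[inc, 1L]),
    jsw_worse_followup = ifelse(left, jsw_l[inc, 2L], jsw_r[inc, 2L]),
    womac_baseline = b$womac_total[inc],
    womac_followup = f$womac_total[inc]
  )
  derived[, womac_change := womac_followup - womac_baseline]
  derived[, group := classify_group(womac_baseline, womac_followup)]
  list(included = ids[inc], log = log, clinical = derived)
}
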