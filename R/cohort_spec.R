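#' Specification of a synthetic accelerometer cohort
#'
#' Bundles and validates every parameter of the synthetic cohort generator:
#' cohort size and worsening prevalence, the wear protocol (days per visit,
#' epoch length), the diurnal activity profile, the non-wear model, the
#' target daily intensity composition, the per-group multiplicative activity
#' declines applied at the follow-up visit, and the WOMAC change model that
#' drives Stable/Worsening group membership.
#'
#' Defaults emulate a 7-day, two-visit hip-worn accelerometer protocol in an
#' older knee-osteoarthritis cohort: overnight device removal (22:00-07:00),
#' sporadic daytime removals, a daily composition of roughly 580 sedentary,
#' 278 light and 20 moderate-to-vigorous minutes, a 15.7% worsening
#' prevalence, and activity declines at follow-up that are concentrated in
#' the late-afternoon and evening clock bins (15:00-21:00) for the worsening
#' group.
#'
#' @param n_participants number of participants.
#' @param worsening_fraction expected proportion of participants whose WOMAC
#'   change exceeds the MCID (>10 points); in `[0, 1]`.
#' @param n_days_per_visit recorded days per visit (protocol: 7).
#' @param epoch_seconds epoch length in seconds; only 60 is supported.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @param diurnal_profile numeric length-24 vector of relative mean activity
#'   levels (counts/min) for clock hours 0-23; all values must be >= 0. The
#'   shape (not the absolute scale) governs how light activity and
#'   moderate-to-vigorous bouts are allocated across the day.
#' @param nonwear_model list with `overnight_start`, `overnight_end` (clock
#'   hours in `[0, 24)`; the device is off from `overnight_start` to
#'   `overnight_end` across midnight), `daytime_rate` (removal events/day),
#'   `daytime_mean_min` and `daytime_shape` (gamma duration model, minutes).
#' @param intensity_mix named numeric `c(sed=, lpa=, mvpa=)` target daily
#'   minutes in each intensity category.
#' @param decline_effects list with numeric length-8 vectors `stable` and
#'   `worsening`: multiplicative factors (> 0) applied to epoch counts at
#'   the follow-up visit, one per 3-hour clock bin (00-03, ..., 21-24).
#' @param womac_model list with `baseline_mean`, `baseline_sd`,
#'   `stable_change_mean`, `stable_change_sd`, `worsening_change_mean`,
#'   `worsening_change_sd` on the 0-96 WOMAC total scale.
#' @param between_person_sd log-scale SD of the lognormal between-person
#'   activity multiplier (constant across visits).
#' @param missing_rates list with elements `jsw`, `kl`, `covariate`:
#'   probabilities of injected missingness exercising the imputation and
#'   exclusion rules.
#' @param knee_replacement_rate probability of a pre-baseline knee
#'   replacement flag (an exclusion).
#'
#' @return an object of class `koa_cohort_spec` (a validated list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_participants = 5, seed = 1)
#' spec$intensity_mix
cohort_spec <- function(n_participants,
                        worsening_fraction = 0.16,
                        n_days_per_visit = 7L,
                        epoch_seconds = 60L,
                        seed = 1L,
                        diurnal_profile = default_diurnal_profile(),
                        nonwear_model = list(
                          overnight_start = 22, overnight_end = 7,
                          daytime_rate = 0.3,
                          daytime_mean_min = 150, daytime_shape = 6
                        ),
                        intensity_mix = c(sed = 580, lpa = 278, mvpa = 20),
                        decline_effects = list(
                          stable    = c(rep(0.86, 5), 0.94, 0.94, 0.86),
                          worsening = c(rep(0.85, 5), 0.79, 0.79, 0.85)
                        ),
                        womac_model = list(
                          baseline_mean = 11.9, baseline_sd = 14.9,
                          stable_change_mean = -1.9, stable_change_sd = 8.1,
                          worsening_change_mean = 19.6, worsening_change_sd = 9.2
                        ),
                        between_person_sd = 0.45,
                        missing_rates = list(jsw = 0.03, kl = 0.02, covariate = 0.01),
                        knee_replacement_rate = 0.02) {
  stop_field <- function(cond, field, msg) {
    if (cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  stop_field(length(n_participants) != 1L || is.na(n_participants) ||
               n_participants < 0 || n_participants != floor(n_participants),
             "n_participants", "must be a single non-negative integer")
  stop_field(!is.numeric(worsening_fraction) || length(worsening_fraction) != 1L ||
               is.na(worsening_fraction) ||
               worsening_fraction < 0 || worsening_fraction > 1,
             "worsening_fraction", "must be a proportion in [0, 1]")
  stop_field(length(n_days_per_visit) != 1L || n_days_per_visit < 1 ||
               n_days_per_visit != floor(n_days_per_visit),
             "n_days_per_visit", "must be a positive integer")
  stop_field(!identical(as.integer(epoch_seconds), 60L),
             "epoch_seconds", "only 60-second epochs are supported")
  stop_field(length(seed) != 1L || is.na(seed) || seed != floor(seed),
             "seed", "must be a single integer")
  stop_field(!is.numeric(diurnal_profile) || length(diurnal_profile) != 24L ||
               anyNA(diurnal_profile) || any(diurnal_profile < 0),
             "diurnal_profile", "must be 24 non-negative per-hour levels")
  nw <- nonwear_model
  stop_field(!is.list(nw) ||
               !all(c("overnight_start", "overnight_end", "daytime_rate",
                      "daytime_mean_min", "daytime_shape") %in% names(nw)),
             "nonwear_model", "missing components")
  stop_field(nw$overnight_start < 0 || nw$overnight_start >= 24 ||
               nw$overnight_end < 0 || nw$overnight_end >= 24,
             "nonwear_model", "overnight window hours must lie in [0, 24)")
  stop_field(nw$daytime_rate < 0 || nw$daytime_mean_min <= 0 || nw$daytime_shape <= 0,
             "nonwear_model", "daytime removal parameters must be positive")
  stop_field(!is.numeric(intensity_mix) ||
               !all(c("sed", "lpa", "mvpa") %in% names(intensity_mix)) ||
               any(intensity_mix < 0),
             "intensity_mix", "needs non-negative named sed/lpa/mvpa minutes")
  stop_field(!is.list(decline_effects) ||
               !all(c("stable", "worsening") %in% names(decline_effects)) ||
               length(decline_effects$stable) != 8L ||
               length(decline_effects$worsening) != 8L ||
               any(unlist(decline_effects) <= 0),
             "decline_effects",
             "needs positive length-8 `stable` and `worsening` factors")
  wm <- womac_model
  stop_field(!is.list(wm) || !all(c(
    "baseline_mean", "baseline_sd", "stable_change_mean", "stable_change_sd",
    "worsening_change_mean", "worsening_change_sd") %in% names(wm)),
    "womac_model", "missing components")
  stop_field(wm$worsening_change_mean <= 10,
             "womac_model", "worsening change mean must exceed the 10-point MCID")
  stop_field(between_person_sd < 0, "between_person_sd", "must be >= 0")
  stop_field(knee_replacement_rate < 0 || knee_replacement_rate > 1,
             "knee_replacement_rate", "must be a probability")

  structure(list(
    n_participants = as.integer(n_participants),
    worsening_fraction = worsening_fraction,
    n_days_per_visit = as.integer(n_days_per_visit),
    epoch_seconds = 60L,
    seed = as.integer(seed),
    diurnal_profile = as.numeric(diurnal_profile),
    nonwear_model = nw,
    intensity_mix = intensity_mix,
    decline_effects = lapply(decline_effects[c("stable", "worsening")], as.numeric),
    womac_model = wm,
    between_person_sd = between_person_sd,
    missing_rates = missing_rates,
    knee_replacement_rate = knee_replacement_rate
  ), class = "koa_cohort_spec")
}

#' Default diurnal activity profile
#'
#' Relative mean activity level (counts/min) by clock hour for an older
#' adult cohort: negligible overnight, a rise through the morning, a broad
#' late-morning plateau and a gradual decline through the afternoon and
#' evening.
#'
#' @return numeric vector of length 24 (hours 0-23).
#' @export
default_diurnal_profile <- function() {
  c(5, 5, 5, 5, 5, 5,         # 00-06
    30, 120, 220, 280,        # 06-10
    300, 290, 270, 260,       # 10-14
    250, 240, 230, 210,       # 14-18
    180, 150, 110, 60,        # 18-22
    20, 8)                    # 22-24
}

#' @export
print.koa_cohort_spec <- function(x, ...) {
  cat("Synthetic accelerometer cohort specification\n")
  cat(sprintf("  participants: %d (worsening fraction %.3f)\n",
              x$n_participants, x$worsening_fraction))
  cat(sprintf("  protocol: %d days/visit x 2 visits, 1-min epochs, seed %d\n",
              x$n_days_per_visit, x$seed))
  cat(sprintf("  overnight off-window: %02d:00-%02d:00; daytime removals %.2f/day\n",
              x$nonwear_model$overnight_start, x$nonwear_model$overnight_end,
              x$nonwear_model$daytime_rate))
  cat(sprintf("  intensity targets (min/day): SED %.0f, LPA %.0f, MVPA %.0f\n",
              x$intensity_mix[["sed"]], x$intensity_mix[["lpa"]],
              x$intensity_mix[["mvpa"]]))
  invisible(x)
}
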