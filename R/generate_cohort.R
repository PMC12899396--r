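#' Generate a synthetic two-visit accelerometer cohort
#'
#' Draws a complete synthetic cohort under a [cohort_spec()]: minute-epoch
#' activity counts and steps for every participant at two visits
#' (`baseline`, `followup`), a participant-visit clinical table, and the
#' ground truth used by parameter-recovery tests.
#'
#' Epoch counts follow a zero-inflated, right-skewed mixture whose
#' allocation across the day tracks the diurnal profile: sedentary epochs
#' are zero-inflated low counts, light-activity epochs draw counts in the
#' light range, and 0-3 contiguous bouts of >= 10 min per day carry elevated
#' counts so moderate-to-vigorous minutes occur in bouts rather than as
#' isolated epochs. At the follow-up visit each epoch's count is thinned
#' binomially by the group- and clock-bin-specific decline factor, so the
#' expected count scales exactly by the factor (factors > 1 add a Poisson
#' top-up instead). True non-wear (overnight window plus sporadic daytime
#' removals) is recorded literally as zero counts and zero steps, and is
#' flagged in the returned truth. Steps are a monotone stochastic function
#' of counts, capped at 130 steps/min and zero whenever counts are zero.
#'
#' WOMAC changes are drawn with support strictly above the 10-point MCID
#' for worsening participants and strictly inside (-10, 10) for stable
#' participants, so the MCID grouping rule recovers the drawn labels
#' exactly.
#'
#' All randomness flows through R's RNG seeded from `spec$seed`; the
#' caller's RNG state is restored on exit. Identical specs give
#' bit-identical output.
#'
#' @param spec a `koa_cohort_spec` from [cohort_spec()].
#' @return list with elements
#'   \describe{
#'     \item{epochs}{`data.table` of minute epochs: `participant_id`,
#'       `visit`, `date` (`IDate`), `minute` (0-1439), `counts`, `steps`,
#'       sorted by participant, visit, date, minute.}
#'     \item{clinical}{`data.table`, one row per participant-visit:
#'       demographics, WOMAC total, CESD, PASE, gait speed, five-times
#'       sit-to-stand, falls, per-knee KL grade and medial minimum JSW,
#'       knee-replacement flag.}
#'     \item{truth}{list: `groups` (participant, group label, drawn WOMAC
#'       change, activity multiplier), `decline` (per group x bin injected
#'       factor), `nonwear` (logical vector aligned with `epochs` rows,
#'       `TRUE` on true non-wear epochs).}
#'   }
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_participants = 2, seed = 42))
#' cohort$epochs[1:3]
#' table(cohort$truth$groups$group)
generate_cohort <- function(spec) {
  if (!inherits(spec, "koa_cohort_spec")) {
    stop("`spec` must be created by cohort_spec()", call. = FALSE)
  }
  if (spec$n_participants == 0L) {
    return(list(
      epochs = empty_epochs(),
      clinical = empty_clinical(),
      truth = list(
        groups = data.table(participant_id = character(),
                            group = character(),
                            womac_change = numeric(),
                            activity_multiplier = numeric()),
        decline = decline_table(spec),
        nonwear = logical()
      )
    ))
  }

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  n <- spec$n_participants
  ids <- sprintf("P%05d", seq_len(n))
  group <- ifelse(runif(n) < spec$worsening_fraction, "worsening", "stable")
  mult <- rlnorm(n, meanlog = -spec$between_person_sd^2 / 2,
                 sdlog = spec$between_person_sd)

  clinical <- draw_clinical(spec, ids, group)

  # habitual weekly schedule (bout times, removal times) shared by both
  # visits; counts are drawn fresh per visit
  schedule <- draw_wear_schedule(spec, n)
  base_ep <- draw_visit_epochs(spec, ids, group, mult, "baseline", schedule)
  fu_ep <- draw_visit_epochs(spec, ids, group, mult, "followup", schedule)
  epochs <- rbind(base_ep$epochs, fu_ep$epochs)
  nonwear <- c(base_ep$nonwear, fu_ep$nonwear)
  ord <- epochs[, order(participant_id, visit, date, minute)]
  epochs <- epochs[ord]
  nonwear <- nonwear[ord]

  list(
    epochs = epochs,
    clinical = clinical$table,
    truth = list(
      groups = data.table(participant_id = ids, group = group,
                          womac_change = clinical$womac_change,
                          activity_multiplier = mult),
      decline = decline_table(spec),
      nonwear = nonwear
    )
  )
}

decline_table <- function(spec) {
  data.table(
    group = rep(c("stable", "worsening"), each = 8L),
    bin = rep(0:7, times = 2L),
    factor = c(spec$decline_effects$stable, spec$decline_effects$worsening)
  )
}

empty_epochs <- function() {
  data.table(participant_id = character(), visit = character(),
             date = as.IDate(integer()), minute = integer(),
             counts = integer(), steps = integer())
}

empty_clinical <- function() {
  draw_clinical(NULL, character(), character())$table
}

# deterministic rejection sampler: redraw until `ok`
rtrunc <- function(n, draw, ok) {
  x <- draw(n)
  bad <- !ok(x)
  while (any(bad)) {
    x[bad] <- draw(sum(bad))
    bad <- !ok(x)
  }
  x
}

gamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = mean / shape)
}

draw_clinical <- function(spec, ids, group) {
  n <- length(ids)
  if (n == 0L) {
    tab <- data.table(
      participant_id = character(), visit = character(), age = numeric(),
      sex = character(), race = character(), bmi = numeric(),
      womac_total = numeric(), cesd = numeric(), pase = numeric(),
      gait_speed = numeric(), fts = numeric(), falls = integer(),
      kl_left = integer(), kl_right = integer(),
      jsw_left = numeric(), jsw_right = numeric(),
      knee_replacement = logical()
    )
    return(list(table = tab, womac_change = numeric()))
  }
  wm <- spec$womac_model
  worsening <- group == "worsening"

  age <- pmin(79, pmax(45, round(rnorm(n, 64.9, 9.1))))
  sex <- ifelse(runif(n) < 0.555, "female", "male")
  race <- sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                 prob = c(0.858, 0.130, 0.005, 0.007))
  bmi <- round(pmax(17, rnorm(n, 28.6, 4.8)), 1)

  womac_b <- rtrunc(n, function(k) gamma_ms(k, wm$baseline_mean, wm$baseline_sd),
                    function(x) x <= 60)
  womac_change <- numeric(n)
  nw <- sum(worsening)
  if (nw > 0) {
    # support strictly above the MCID, capped so follow-up stays on-scale
    extra_mean <- wm$worsening_change_mean - 10
    womac_change[worsening] <- rtrunc(
      nw, function(k) 10 + gamma_ms(k, extra_mean, wm$worsening_change_sd),
      function(x) x <= 35)
  }
  ns <- sum(!worsening)
  if (ns > 0) {
    base_s <- womac_b[!worsening]
    womac_change[!worsening] <- rtrunc(
      ns, function(k) rnorm(k, wm$stable_change_mean, wm$stable_change_sd),
      function(x) abs(x) < 10 & base_s + x >= 0)
  }
  womac_f <- womac_b + womac_change

  cesd_b <- gamma_ms(n, 6.3, 7.2)
  cesd_f <- pmax(0, cesd_b + rnorm(n, ifelse(worsening, 0.3, -0.2), 6))
  pase_b <- pmax(0, rnorm(n, 159.6, 80.9))
  pase_f <- pmax(0, pase_b + rnorm(n, ifelse(worsening, -1.4, 1.7), 70))
  gait_b <- pmax(0.4, rnorm(n, 1.34, 0.20))
  gait_f <- pmax(0.3, gait_b + rnorm(n, ifelse(worsening, -0.067, -0.015),
                                     ifelse(worsening, 0.14, 0.11)))
  fts_b <- pmax(3, rnorm(n, ifelse(worsening, 11.53, 10.50),
                         ifelse(worsening, 5.00, 3.95)))
  fts_f <- pmax(3, fts_b + rnorm(n, ifelse(worsening, 0.563, -0.034), 2))
  falls_b <- rpois(n, 0.3)
  falls_f <- rpois(n, 0.3)

  kl_probs <- c(0.10, 0.14, 0.35, 0.28, 0.13) # ~76% with KL >= 2
  kl_l_b <- sample(0:4, n, replace = TRUE, prob = kl_probs)
  kl_r_b <- sample(0:4, n, replace = TRUE, prob = kl_probs)
  kl_l_f <- pmin(4L, kl_l_b + rbinom(n, 1, 0.06))
  kl_r_f <- pmin(4L, kl_r_b + rbinom(n, 1, 0.06))
  jsw_from_kl <- function(kl) pmax(0.5, rnorm(n, 4.6 - 0.4 * kl, 1.2))
  jsw_l_b <- jsw_from_kl(kl_l_b)
  jsw_r_b <- jsw_from_kl(kl_r_b)
  jsw_change <- function() rnorm(n, ifelse(worsening, -0.13, -0.05), 0.4)
  jsw_l_f <- pmax(0.2, jsw_l_b + jsw_change())
  jsw_r_f <- pmax(0.2, jsw_r_b + jsw_change())

  knee_replacement <- runif(n) < spec$knee_replacement_rate

  # injected missingness exercising imputation/carry-forward/exclusions
  mr <- spec$missing_rates
  jsw_l_b[runif(n) < mr$jsw] <- NA_real_
  jsw_r_f[runif(n) < mr$jsw] <- NA_real_
  kl_l_f[runif(n) < mr$kl] <- NA_integer_
  kl_r_f[runif(n) < mr$kl] <- NA_integer_
  bmi[runif(n) < mr$covariate] <- NA_real_

  tab <- rbind(
    data.table(participant_id = ids, visit = "baseline", age = age, sex = sex,
               race = race, bmi = bmi, womac_total = womac_b, cesd = cesd_b,
               pase = pase_b, gait_speed = gait_b, fts = fts_b,
               falls = falls_b, kl_left = as.integer(kl_l_b),
               kl_right = as.integer(kl_r_b), jsw_left = jsw_l_b,
               jsw_right = jsw_r_b, knee_replacement = knee_replacement),
    data.table(participant_id = ids, visit = "followup", age = age + 2,
               sex = sex, race = race, bmi = bmi, womac_total = womac_f,
               cesd = cesd_f, pase = pase_f, gait_speed = gait_f, fts = fts_f,
               falls = falls_f, kl_left = as.integer(kl_l_f),
               kl_right = as.integer(kl_r_f), jsw_left = jsw_l_f,
               jsw_right = jsw_r_f, knee_replacement = knee_replacement)
  )
  setkey(tab, participant_id, visit)
  list(table = tab, womac_change = womac_change)
}

# habitual wear schedule: epoch indices (within the participant x day x
# minute grid) of daytime removals and of elevated-mean bouts, drawn once
# and shared by both visits — within-person diurnal timing is stable over
# a 2-year interval, so removal and exercise habits recur
draw_wear_schedule <- function(spec, n) {
  days <- spec$n_days_per_visit
  nw <- spec$nonwear_model
  profile <- spec$diurnal_profile
  os <- nw$overnight_start; oe <- nw$overnight_end
  nd <- n * days

  removal_idx <- integer(0)
  n_ev <- rpois(nd, nw$daytime_rate)
  tot_ev <- sum(n_ev)
  if (tot_ev > 0) {
    day_lo <- if (os > oe) oe * 60L else 0L
    day_hi <- if (os > oe) os * 60L else 1440L
    ev_day <- rep(seq_len(nd), n_ev) # index into participant-day blocks
    ev_start <- floor(runif(tot_ev, day_lo, day_hi - 30))
    ev_dur <- pmax(20, round(gamma_ms(tot_ev, nw$daytime_mean_min,
                                      nw$daytime_mean_min / sqrt(nw$daytime_shape))))
    ev_end <- pmin(ev_start + ev_dur, day_hi) # exclusive
    lens <- ev_end - ev_start
    base <- (ev_day - 1L) * 1440L + ev_start # 0-based row offset
    removal_idx <- rep(base, lens) + sequence(lens) # 1-based rows
  }

  bout_idx <- integer(0)
  nb <- sample(0:3, nd, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  tot_b <- sum(nb)
  if (tot_b > 0) {
    b_day <- rep(seq_len(nd), nb)
    bout_minutes <- 480:1230
    w <- profile[bout_minutes %/% 60L + 1L]
    b_start <- sample(bout_minutes, tot_b, replace = TRUE, prob = w)
    b_len <- sample(10:25, tot_b, replace = TRUE)
    b_end <- pmin(b_start + b_len, 1320L)
    lens <- b_end - b_start
    base <- (b_day - 1L) * 1440L + b_start
    bout_idx <- rep(base, lens) + sequence(lens)
  }

  list(removal_idx = removal_idx, bout_idx = bout_idx)
}

# epoch engine: one visit for the whole cohort, vectorised over
# participant x day x minute
draw_visit_epochs <- function(spec, ids, group, mult, visit, schedule) {
  n <- length(ids)
  days <- spec$n_days_per_visit
  nw <- spec$nonwear_model
  profile <- spec$diurnal_profile

  grid <- CJ(pi_ = seq_len(n), day = seq_len(days), minute = 0:1439)
  nr <- nrow(grid)
  hour <- grid$minute %/% 60L

  # true non-wear: overnight window (possibly spanning midnight) plus the
  # habitual daytime removals
  os <- nw$overnight_start; oe <- nw$overnight_end
  overnight <- if (os > oe) hour >= os | hour < oe else hour >= os & hour < oe
  true_nonwear <- overnight
  true_nonwear[schedule$removal_idx] <- TRUE

  worn <- !true_nonwear

  bout <- logical(nr)
  bout[schedule$bout_idx] <- TRUE
  bout <- bout & worn

  counts <- integer(nr)
  i_bout <- which(bout)
  if (length(i_bout)) {
    counts[i_bout] <- 400L + rnbinom(length(i_bout), mu = 2800, size = 6)
  }

  # light-activity epoch probability per hour, scaled so expected daily LPA
  # minutes match the intensity target, then by the participant multiplier
  worn_hours <- setdiff(0:23, if (os > oe) c(os:23, 0:(oe - 1)) else os:(oe - 1))
  c_l <- spec$intensity_mix[["lpa"]] / (60 * sum(profile[worn_hours + 1L]))
  i_rest <- which(worn & !bout)
  if (length(i_rest)) {
    p_lpa <- pmin(0.92, c_l * profile[hour[i_rest] + 1L] *
                    mult[grid$pi_[i_rest]])
    is_lpa <- runif(length(i_rest)) < p_lpa
    i_lpa <- i_rest[is_lpa]
    i_sed <- i_rest[!is_lpa]
    counts[i_lpa] <- 100L + rnbinom(length(i_lpa), mu = 400, size = 1.6)
    nonzero <- runif(length(i_sed)) >= 0.45
    i_snz <- i_sed[nonzero]
    counts[i_snz] <- 1L + rnbinom(length(i_snz), mu = 16, size = 0.6)
  }

  if (visit == "followup") {
    fac <- rbind(spec$decline_effects$stable, spec$decline_effects$worsening)
    gi <- (group == "worsening") + 1L
    f <- fac[cbind(gi[grid$pi_], hour %/% 3L + 1L)]
    pos <- which(counts > 0L)
    fp <- f[pos]
    thin <- fp <= 1
    new <- counts[pos]
    if (any(thin)) {
      new[thin] <- rbinom(sum(thin), counts[pos][thin], fp[thin])
    }
    if (any(!thin)) {
      up <- !thin
      new[up] <- counts[pos][up] +
        rpois(sum(up), counts[pos][up] * (fp[up] - 1))
    }
    counts[pos] <- new
  }

  counts <- as.integer(counts)
  steps <- integer(nr)
  pos <- which(counts > 0L)
  if (length(pos)) {
    steps[pos] <- as.integer(
      pmin(130, rpois(length(pos), 120 * counts[pos] / (counts[pos] + 1500))))
  }

  start_date <- as.IDate(if (visit == "baseline") "2008-03-03" else "2010-03-01")
  epochs <- data.table(
    participant_id = ids[grid$pi_],
    visit = visit,
    date = start_date + grid$day - 1L,
    minute = grid$minute,
    counts = counts,
    steps = steps
  )
  list(epochs = epochs, nonwear = true_nonwear)
}
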