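# Epoch-level cohort generator: the middle fidelity tier.  Emits per-epoch
# ENMO + wear flags directly (no raw signal), cheap enough for cohorts of
# hundreds of subjects over a week, used by the end-to-end pipeline.

#' Configuration for the epoch-level cohort generator
#'
#' Each subject gets a minute-level behavioural state chain (shared with the
#' raw-signal tier), a log-normal activity multiplier (between-subject
#' heterogeneity), log-normal day multipliers (day-to-day variation) and
#' log-normal epoch noise.  Weekends scale the probability of moving into
#' light/MVPA states by `weekend_activity_factor` (< 1 reproduces the
#' "less activity at the weekend" adult pattern).  Occasional non-wear gaps
#' exercise the valid-day filter downstream.
#'
#' @param n_subjects,n_days Cohort dimensions (>= 2 each).
#' @param epoch_len Epoch length, s (default 5).
#' @param start_date First monitored day (a `Date`); all subjects start on it.
#' @param activity_state_rates See [default_state_rates()].
#' @param state_enmo_levels Mean ENMO per state, mg.
#' @param subject_sd_log SD of the per-subject log multiplier.
#' @param day_sd_log SD of the per-day log multiplier.
#' @param epoch_sd_log SD of the per-epoch log noise.
#' @param weekend_activity_factor Multiplier on weekend transition
#'   probabilities into light/MVPA (> 0).
#' @param nonwear_day_prob Probability that a subject-day contains one
#'   non-wear gap.
#' @param nonwear_hours_range Length-2, uniform range of gap duration (h).
#' @param seed Integer root seed (one child stream per subject).
#' @return A validated list of class `epoch_sim_config`.
#' @export
epoch_sim_config <- function(n_subjects = 100, n_days = 7, epoch_len = 5,
                             start_date = as.Date("2012-03-05"),
                             activity_state_rates = default_state_rates(),
                             state_enmo_levels = c(sleep = 3, sedentary = 15,
                                                   light = 70, mvpa = 180),
                             subject_sd_log = 0.25, day_sd_log = 0.15,
                             epoch_sd_log = 0.6,
                             weekend_activity_factor = 0.75,
                             nonwear_day_prob = 0.10,
                             nonwear_hours_range = c(1, 9),
                             seed = 1L) {
  if (!is_count(n_subjects, min = 2)) stop_config("n_subjects", "must be an integer >= 2")
  if (!is_count(n_days, min = 2)) stop_config("n_days", "must be an integer >= 2")
  if (!is_number(epoch_len) || epoch_len <= 0 || 86400 %% epoch_len != 0)
    stop_config("epoch_len", "must be > 0 and divide 86400 s")
  check_rates(activity_state_rates)
  if (length(state_enmo_levels) != 4 || any(state_enmo_levels < 0))
    stop_config("state_enmo_levels", "must be 4 non-negative means (mg)")
  for (f in c("subject_sd_log", "day_sd_log", "epoch_sd_log"))
    if (!is_number(get(f), min = 0)) stop_config(f, "must be >= 0")
  if (!is_number(weekend_activity_factor) || weekend_activity_factor <= 0)
    stop_config("weekend_activity_factor", "must be > 0")
  if (!is_number(nonwear_day_prob, min = 0) || nonwear_day_prob > 1)
    stop_config("nonwear_day_prob", "must be in [0, 1]")
  if (length(nonwear_hours_range) != 2 || any(nonwear_hours_range <= 0) ||
      nonwear_hours_range[1] > nonwear_hours_range[2] || nonwear_hours_range[2] > 24)
    stop_config("nonwear_hours_range", "must be increasing within (0, 24]")
  if (!is_count(seed, min = 0)) stop_config("seed", "must be a non-negative integer")
  structure(
    list(n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
         epoch_len = epoch_len, start_date = as.Date(start_date),
         activity_state_rates = activity_state_rates,
         state_enmo_levels = state_enmo_levels[c("sleep", "sedentary", "light", "mvpa")],
         subject_sd_log = subject_sd_log, day_sd_log = day_sd_log,
         epoch_sd_log = epoch_sd_log,
         weekend_activity_factor = weekend_activity_factor,
         nonwear_day_prob = nonwear_day_prob,
         nonwear_hours_range = nonwear_hours_range,
         seed = as.integer(seed)),
    class = "epoch_sim_config"
  )
}

#' Simulate one subject's epoch-level ENMO series
#'
#' @param cfg An [epoch_sim_config()].
#' @param subject_index Which subject stream to generate (1-based); the
#'   subject's child seed is derived from `cfg$seed`, so any subject can be
#'   regenerated alone.
#' @return An [epoch_series()] spanning `cfg$n_days` full calendar days; its
#'   `$truth` holds the subject multiplier, day multipliers, minute-level
#'   state chain and injected non-wear epochs.
#' @export
simulate_epoch_series <- function(cfg, subject_index = 1L) {
  if (!inherits(cfg, "epoch_sim_config"))
    stop_config("cfg", "must be built with epoch_sim_config()")
  if (!is_count(subject_index) || subject_index > cfg$n_subjects)
    stop_config("subject_index", "must be in 1..n_subjects")
  seed_i <- child_seeds(cfg$seed, cfg$n_subjects)[subject_index]
  with_seed(seed_i, {
    n_min <- cfg$n_days * 1440L
    epd <- as.integer(86400 / cfg$epoch_len)  # epochs per day
    n_ep <- cfg$n_days * epd
    ep_per_min <- as.integer(60 / cfg$epoch_len)

    dates <- cfg$start_date + seq_len(cfg$n_days) - 1
    dow <- iso_dow(dates)
    mod <- (seq_len(n_min) - 1) %% 1440
    wk_min <- rep(is_weekend(dow), each = 1440L)
    states <- simulate_state_minutes(cfg$activity_state_rates, mod, wk_min,
                                     cfg$weekend_activity_factor)

    mult_subject <- exp(rnorm(1, 0, cfg$subject_sd_log))
    mult_day <- exp(rnorm(cfg$n_days, 0, cfg$day_sd_log))
    lev <- cfg$state_enmo_levels[states]            # per minute
    lev_ep <- rep(lev, each = ep_per_min)           # per epoch
    day_ep <- rep(seq_len(cfg$n_days), each = epd)
    enmo <- lev_ep * mult_subject * mult_day[day_ep] *
      exp(rnorm(n_ep, 0, cfg$epoch_sd_log))

    nonwear <- rep(FALSE, n_ep)
    gaps <- list()
    has_gap <- runif(cfg$n_days) < cfg$nonwear_day_prob
    for (d in which(has_gap)) {
      dur_h <- runif(1, cfg$nonwear_hours_range[1], cfg$nonwear_hours_range[2])
      st_h <- runif(1, 0, 24 - dur_h)
      i0 <- (d - 1L) * epd + floor(st_h * 3600 / cfg$epoch_len) + 1
      i1 <- min(d * epd, (d - 1L) * epd + ceiling((st_h + dur_h) * 3600 / cfg$epoch_len))
      nonwear[i0:i1] <- TRUE
      gaps[[length(gaps) + 1]] <- c(day = d, start_h = st_h, duration_h = dur_h)
    }
    enmo[nonwear] <- 0

    epoch_series(sprintf("S%04d", subject_index), cfg$epoch_len,
                 as.POSIXct(paste(dates[1], "00:00:00"), tz = "UTC"),
                 enmo, nonwear = nonwear,
                 truth = list(mult_subject = mult_subject, mult_day = mult_day,
                              state_minutes = states, nonwear_gaps = gaps,
                              dates = dates, day_of_week = dow))
  })
}
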