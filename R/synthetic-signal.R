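# Raw-signal generator: the slow, high-fidelity tier.  Hours of tri-axial
# signal with known calibration error, non-wear gaps, spikes and per-epoch
# ground-truth ENMO, for validating the signal-processing stage.

#' Default minute-level activity-state transition probabilities
#'
#' Per-minute transition probabilities between the four behavioural states
#' `sleep`, `sedentary`, `light`, `mvpa`, split into a daytime and a
#' night-time regime (night hours pull the chain into sleep and suppress
#' activity).  Rows are "from", columns "to"; rows sum to 1.
#'
#' @param night_hours Numeric length-2: local hour at which the night regime
#'   starts and ends (default 23 to 7).
#' @return List with elements `day`, `night` (4x4 matrices) and `night_hours`.
#' @export
default_state_rates <- function(night_hours = c(23, 7)) {
  states <- c("sleep", "sedentary", "light", "mvpa")
  day <- matrix(c(
    # to:  sleep  sedentary light  mvpa
    0.955, 0.040, 0.005, 0.000,  # from sleep
    0.002, 0.908, 0.080, 0.010,  # from sedentary
    0.000, 0.150, 0.820, 0.030,  # from light
    0.000, 0.050, 0.150, 0.800   # from mvpa
  ), 4, 4, byrow = TRUE, dimnames = list(states, states))
  night <- matrix(c(
    0.998, 0.002, 0.000, 0.000,
    0.300, 0.680, 0.020, 0.000,
    0.100, 0.500, 0.400, 0.000,
    0.000, 0.500, 0.400, 0.100
  ), 4, 4, byrow = TRUE, dimnames = list(states, states))
  list(day = day, night = night, night_hours = night_hours)
}

check_rates <- function(r) {
  ok <- function(m) is.matrix(m) && all(dim(m) == 4) && all(m >= 0) &&
    all(abs(rowSums(m) - 1) < 1e-8)
  if (!is.list(r) || !ok(r$day) || !ok(r$night) ||
      !is.numeric(r$night_hours) || length(r$night_hours) != 2)
    stop_config("activity_state_rates",
                "must be a list(day, night, night_hours) of 4x4 row-stochastic matrices")
  invisible(r)
}

#' Configuration for the raw-signal generator
#'
#' @param sample_rate Sampling frequency, Hz (> 0; 85.7 matches the wrist
#'   device the defaults emulate).
#' @param days Recording span in days (may be fractional).
#' @param start_time `POSIXct` recording start.
#' @param activity_state_rates Minute-level state transition model, see
#'   [default_state_rates()].
#' @param state_enmo_levels Named numeric, mean true ENMO per state in mg
#'   (non-negative), names `sleep`, `sedentary`, `light`, `mvpa`.
#' @param axis_offsets Length-3 numeric, per-axis calibration offset in g
#'   added to the measured signal.
#' @param axis_gains Length-3 numeric, per-axis gain error (> 0); the
#'   measured signal is `true / gain + offset`, so that a downstream
#'   calibration `(measured - offset) * gain` recovers the truth.
#' @param nonwear_windows List of `c(start_h, duration_h)` pairs (hours from
#'   recording start); within them the device lies perfectly still with no
#'   sensor noise.
#' @param spike_rate Expected artifact spikes per day (Poisson); each spike
#'   sets one axis of one sample beyond the +/- 8 g dynamic range.
#' @param noise_sd Per-axis white sensor noise SD in g (default 0.003).
#' @param orientation_walk_sd Per-minute SD of the slow orientation random
#'   walk (radians-ish; 0 freezes orientation).
#' @param epoch_len Epoch length used for the ground-truth ENMO track, s.
#' @param seed Integer RNG seed.
#' @return A validated list of class `signal_sim_config`.
#' @export
signal_sim_config <- function(sample_rate = 85.7, days = 1,
                              start_time = as.POSIXct("2012-03-05 00:00:00", tz = "UTC"),
                              activity_state_rates = default_state_rates(),
                              state_enmo_levels = c(sleep = 3, sedentary = 15,
                                                    light = 70, mvpa = 180),
                              axis_offsets = c(0, 0, 0),
                              axis_gains = c(1, 1, 1),
                              nonwear_windows = list(),
                              spike_rate = 0, noise_sd = 0.003,
                              orientation_walk_sd = 0.05,
                              epoch_len = 5, seed = 1L) {
  if (!is_number(sample_rate) || sample_rate <= 0)
    stop_config("sample_rate", "must be > 0 (Hz)")
  if (!is_number(days) || days <= 0) stop_config("days", "must be > 0")
  check_rates(activity_state_rates)
  if (length(state_enmo_levels) != 4 || any(state_enmo_levels < 0) ||
      !all(c("sleep", "sedentary", "light", "mvpa") %in% names(state_enmo_levels)))
    stop_config("state_enmo_levels",
                "must be a non-negative named vector for sleep/sedentary/light/mvpa (mg)")
  if (length(axis_offsets) != 3 || any(!is.finite(axis_offsets)))
    stop_config("axis_offsets", "must be 3 finite numbers (g)")
  if (length(axis_gains) != 3 || any(!is.finite(axis_gains)) || any(axis_gains <= 0))
    stop_config("axis_gains", "must be 3 positive numbers")
  span_h <- days * 24
  for (w in nonwear_windows) {
    if (length(w) != 2 || w[1] < 0 || w[2] <= 0 || w[1] + w[2] > span_h)
      stop_config("nonwear_windows",
                  sprintf("each window must be c(start_h, duration_h) within the %g-h span", span_h))
  }
  if (!is_number(spike_rate, min = 0)) stop_config("spike_rate", "must be >= 0")
  if (!is_number(noise_sd, min = 0)) stop_config("noise_sd", "must be >= 0")
  if (!is_number(orientation_walk_sd, min = 0))
    stop_config("orientation_walk_sd", "must be >= 0")
  if (!is_number(epoch_len) || epoch_len <= 0) stop_config("epoch_len", "must be > 0")
  if (!is_count(seed, min = 0)) stop_config("seed", "must be a non-negative integer")
  structure(
    list(sample_rate = sample_rate, days = days,
         start_time = as.POSIXct(start_time, tz = "UTC"),
         activity_state_rates = activity_state_rates,
         state_enmo_levels = state_enmo_levels[c("sleep", "sedentary", "light", "mvpa")],
         axis_offsets = axis_offsets, axis_gains = axis_gains,
         nonwear_windows = nonwear_windows, spike_rate = spike_rate,
         noise_sd = noise_sd, orientation_walk_sd = orientation_walk_sd,
         epoch_len = epoch_len, seed = as.integer(seed)),
    class = "signal_sim_config"
  )
}

# Minute-level state chain shared by the raw and epoch tiers.
# minute_of_day: 0-based minute within the local day for each simulated minute;
# weekend: logical per minute.  Extra args allow weekend scaling of the
# probabilities of moving into light/mvpa.
simulate_state_minutes <- function(rates, minute_of_day, weekend = NULL,
                                   weekend_activity_factor = 1) {
  n <- length(minute_of_day)
  weekend <- weekend %||% rep(FALSE, n)
  nh <- rates$night_hours
  hour <- minute_of_day / 60
  night <- if (nh[1] > nh[2]) (hour >= nh[1] | hour < nh[2]) else
    (hour >= nh[1] & hour < nh[2])

  scale_into_activity <- function(m, f) {
    if (f == 1) return(m)
    m2 <- m
    m2[, c("light", "mvpa")] <- m2[, c("light", "mvpa")] * f
    # put the removed mass back on the diagonal
    diag(m2) <- diag(m2) + (rowSums(m) - rowSums(m2))
    m2
  }
  mats <- list(
    d_wd = rates$day, n_wd = rates$night,
    d_we = scale_into_activity(rates$day, weekend_activity_factor),
    n_we = scale_into_activity(rates$night, weekend_activity_factor)
  )
  cums <- lapply(mats, function(m) t(apply(m, 1, cumsum)))
  mi <- 1L + night + 2L * weekend  # 1 d_wd, 2 n_wd, 3 d_we, 4 n_we

  u <- runif(n)
  st <- integer(n)
  s <- if (night[1]) 1L else 2L  # start asleep at night, sedentary by day
  for (t in seq_len(n)) {
    row <- cums[[mi[t]]][s, ]
    s <- 1L + (u[t] > row[1]) + (u[t] > row[2]) + (u[t] > row[3])
    st[t] <- s
  }
  st
}

# Random unit vector / renormalised orientation walk.
runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Simulate a raw tri-axial wrist recording with known ground truth
#'
#' Builds a minute-level behavioural state sequence (sleep, sedentary, light,
#' MVPA) from a time-of-day-dependent Markov chain, then synthesises the
#' signal sample by sample: a slowly re-orienting unit-gravity vector whose
#' magnitude is modulated by a non-negative activity deviation with
#' state-dependent mean (so the true per-sample ENMO is known exactly), plus
#' white sensor noise.  Calibration error is applied last
#' (`measured = true / gain + offset`); non-wear windows are perfectly still
#' and noise-free; spike artifacts push single samples beyond +/- 8 g.
#'
#' @param cfg A [signal_sim_config()].
#' @param subject_id Subject label.
#' @return A [raw_recording()] whose `$truth` holds, per ground-truth epoch of
#'   `cfg$epoch_len` seconds: `enmo` (true mean ENMO, mg, pre-noise and
#'   pre-miscalibration), `state` (modal state), `nonwear` (logical), plus
#'   `spike_index` (sample indices of injected spikes) and `state_minutes`
#'   (the minute-level chain).
#' @export
simulate_raw_recording <- function(cfg, subject_id = "SIM") {
  if (!inherits(cfg, "signal_sim_config"))
    stop_config("cfg", "must be built with signal_sim_config()")
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate
    n_min <- ceiling(cfg$days * 1440)
    n <- round(cfg$days * 86400 * fs)
    start_mod <- (as.numeric(cfg$start_time) %% 86400) / 60
    mod <- (start_mod + seq_len(n_min) - 1) %% 1440
    states_min <- simulate_state_minutes(cfg$activity_state_rates, mod)

    # per-sample state
    samp_min <- pmin(floor((seq_len(n) - 1) / (60 * fs)) + 1, n_min)
    state <- states_min[samp_min]

    # orientation: minute-anchored random walk on the unit sphere,
    # linearly interpolated per sample and renormalised
    anchors <- matrix(NA_real_, n_min + 1, 3)
    anchors[1, ] <- runit()
    if (cfg$orientation_walk_sd > 0) {
      steps <- matrix(rnorm(3 * n_min, 0, cfg$orientation_walk_sd), n_min, 3)
      for (m in seq_len(n_min)) {
        v <- anchors[m, ] + steps[m, ]
        anchors[m + 1, ] <- v / sqrt(sum(v^2))
      }
    } else {
      anchors[-1, ] <- matrix(anchors[1, ], n_min, 3, byrow = TRUE)
    }
    tt <- (seq_len(n) - 1) / (60 * fs)  # in minutes
    ax <- approx(0:n_min, anchors[, 1], xout = tt, rule = 2)$y
    ay <- approx(0:n_min, anchors[, 2], xout = tt, rule = 2)$y
    az <- approx(0:n_min, anchors[, 3], xout = tt, rule = 2)$y
    nrm <- sqrt(ax^2 + ay^2 + az^2)
    ax <- ax / nrm; ay <- ay / nrm; az <- az / nrm

    # non-negative activity magnitude deviation, state-dependent mean
    lev_g <- cfg$state_enmo_levels[state] / 1000
    m_dev <- lev_g * rgamma(n, shape = 2, rate = 2)  # mean 1, always >= 0

    nonwear_samp <- rep(FALSE, n)
    for (w in cfg$nonwear_windows) {
      i0 <- floor(w[1] * 3600 * fs) + 1
      i1 <- min(n, floor((w[1] + w[2]) * 3600 * fs))
      if (i1 >= i0) {
        nonwear_samp[i0:i1] <- TRUE
        # frozen orientation, no movement
        ax[i0:i1] <- ax[i0]; ay[i0:i1] <- ay[i0]; az[i0:i1] <- az[i0]
      }
    }
    m_dev[nonwear_samp] <- 0

    mag <- 1 + m_dev
    x <- ax * mag; y <- ay * mag; z <- az * mag
    if (cfg$noise_sd > 0) {
      wearing <- !nonwear_samp
      nw <- sum(wearing)
      x[wearing] <- x[wearing] + rnorm(nw, 0, cfg$noise_sd)
      y[wearing] <- y[wearing] + rnorm(nw, 0, cfg$noise_sd)
      z[wearing] <- z[wearing] + rnorm(nw, 0, cfg$noise_sd)
    }

    spike_index <- integer(0)
    n_spikes <- if (cfg$spike_rate > 0) rpois(1, cfg$spike_rate * cfg$days) else 0L
    if (n_spikes > 0) {
      cand <- which(!nonwear_samp)
      spike_index <- sort(sample(cand, min(n_spikes, length(cand))))
      axis_pick <- sample(3, length(spike_index), replace = TRUE)
      sgn <- sample(c(-1, 1), length(spike_index), replace = TRUE)
      val <- sgn * runif(length(spike_index), 10, 14)
      x[spike_index[axis_pick == 1]] <- val[axis_pick == 1]
      y[spike_index[axis_pick == 2]] <- val[axis_pick == 2]
      z[spike_index[axis_pick == 3]] <- val[axis_pick == 3]
    }

    # miscalibration applied to the measured signal
    x <- x / cfg$axis_gains[1] + cfg$axis_offsets[1]
    y <- y / cfg$axis_gains[2] + cfg$axis_offsets[2]
    z <- z / cfg$axis_gains[3] + cfg$axis_offsets[3]

    # ground-truth epoch track (pre-noise, pre-miscalibration)
    spe <- round(cfg$epoch_len * fs)
    n_ep <- floor(n / spe)
    if (n_ep > 0) {
      idx <- seq_len(n_ep * spe)
      g <- rep(seq_len(n_ep), each = spe)
      true_enmo <- as.numeric(tapply(m_dev[idx] * 1000, g, mean))
      ep_state_mode <- as.integer(tapply(state[idx], g, function(s) {
        tb <- tabulate(s, 4); which.max(tb)
      }))
      ep_nonwear <- as.numeric(tapply(nonwear_samp[idx], g, mean)) > 0.5
    } else {
      true_enmo <- numeric(0); ep_state_mode <- integer(0); ep_nonwear <- logical(0)
    }

    raw_recording(subject_id, fs, cfg$start_time, x, y, z,
                  truth = list(
                    epoch_len = cfg$epoch_len,
                    enmo = true_enmo,
                    state = c("sleep", "sedentary", "light", "mvpa")[ep_state_mode],
                    nonwear = ep_nonwear,
                    spike_index = spike_index,
                    state_minutes = states_min,
                    axis_offsets = cfg$axis_offsets,
                    axis_gains = cfg$axis_gains))
  })
}

#' Simulate a still multi-orientation recording for calibration testing
#'
#' Produces a sequence of motionless segments, each at a fresh uniformly
#' random orientation of the unit-gravity vector, with white sensor noise,
#' then applies a known calibration error (`measured = true / gain + offset`).
#' This is the orientation-rich input [autocalibrate()] needs to recover the
#' injected offsets and gains.
#'
#' @param n_orientations Number of still segments.
#' @param segment_s Duration of each segment, seconds.
#' @param sample_rate Hz.
#' @param noise_sd Per-axis noise SD, g.
#' @param axis_offsets,axis_gains Injected calibration error.
#' @param start_time Recording start.
#' @param seed RNG seed.
#' @param subject_id Subject label.
#' @return A [raw_recording()]; `$truth` records the injected error.
#' @export
simulate_still_recording <- function(n_orientations = 60, segment_s = 60,
                                     sample_rate = 40, noise_sd = 0.003,
                                     axis_offsets = c(0, 0, 0),
                                     axis_gains = c(1, 1, 1),
                                     start_time = as.POSIXct("2012-03-05 00:00:00", tz = "UTC"),
                                     seed = 1L, subject_id = "CAL") {
  with_seed(seed, {
    spe <- round(segment_s * sample_rate)
    n <- n_orientations * spe
    ori <- t(vapply(seq_len(n_orientations), function(i) runit(), numeric(3)))
    x <- rep(ori[, 1], each = spe) + rnorm(n, 0, noise_sd)
    y <- rep(ori[, 2], each = spe) + rnorm(n, 0, noise_sd)
    z <- rep(ori[, 3], each = spe) + rnorm(n, 0, noise_sd)
    x <- x / axis_gains[1] + axis_offsets[1]
    y <- y / axis_gains[2] + axis_offsets[2]
    z <- z / axis_gains[3] + axis_offsets[3]
    raw_recording(subject_id, sample_rate, start_time, x, y, z,
                  truth = list(axis_offsets = axis_offsets,
                               axis_gains = axis_gains))
  })
}
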