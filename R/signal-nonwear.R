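# Non-wear detection: sustained near-zero movement on most axes means the
# device is lying on a table, not on a wrist.

#' Detect non-wear periods
#'
#' Slides a long window (default 60 min, stepping 15 min) over the signal; a
#' window votes non-wear when, on at least `axes_required` of the three axes,
#' the per-axis standard deviation is below `sd_threshold` AND the per-axis
#' value range is below `range_threshold`.  An epoch is non-wear if any
#' window covering it votes non-wear (so detected gaps bleed up to one
#' window into their surroundings -- the price of the sliding design).
#'
#' For a [raw_recording()] the criteria are evaluated on the raw per-axis
#' signal (the standard definition).  For an [epoch_series()], where the
#' per-axis signal is gone, the same window/vote machinery is applied to the
#' epoch ENMO values as a documented approximation.
#'
#' @param x A [raw_recording()] or [epoch_series()].
#' @param epoch_len Epoch length (s) for the returned flags (raw method only).
#' @param window_min Window length, minutes.
#' @param step_min Step between window starts, minutes.
#' @param sd_threshold Per-axis SD threshold, mg (default 13).
#' @param range_threshold Per-axis range threshold, mg (default 50).
#' @param axes_required How many axes must be still (default 2 of 3).
#' @param ... Passed between methods.
#' @return A logical vector, one element per epoch, `TRUE` = non-wear.  If
#'   the input is shorter than one window, all epochs are returned as wear
#'   with a warning.
#' @export
detect_nonwear <- function(x, ...) UseMethod("detect_nonwear")

#' @rdname detect_nonwear
#' @export
detect_nonwear.raw_recording <- function(x, epoch_len = 5, window_min = 60,
                                         step_min = 15, sd_threshold = 13,
                                         range_threshold = 50,
                                         axes_required = 2, ...) {
  spe <- round(epoch_len * x$sample_rate)
  n_ep <- floor(n_samples(x) / spe)
  if (n_ep < 1) stop_input("detect_nonwear: recording shorter than one epoch")
  idx <- seq_len(n_ep * spe)
  ep_stats <- function(v) {
    m <- matrix(v[idx], spe, n_ep)
    list(sum = colSums(m), sumsq = colSums(m^2),
         min = apply(m, 2, min), max = apply(m, 2, max))
  }
  stats <- list(ep_stats(x$x), ep_stats(x$y), ep_stats(x$z))
  nonwear_vote(stats, spe, n_ep, epoch_len, window_min, step_min,
               sd_threshold, range_threshold, axes_required)
}

#' @rdname detect_nonwear
#' @export
detect_nonwear.epoch_series <- function(x, window_min = 60, step_min = 15,
                                        sd_threshold = 13,
                                        range_threshold = 50, ...) {
  n_ep <- length(x$enmo)
  stats <- list(list(sum = x$enmo, sumsq = x$enmo^2, min = x$enmo, max = x$enmo))
  nonwear_vote(stats, 1L, n_ep, x$epoch_len, window_min, step_min,
               sd_threshold, range_threshold, axes_required = 1)
}

# Shared window/vote machinery on per-epoch summary stats (values in the
# same unit as the thresholds are mg when spe refers to g-values * 1000; the
# raw method passes g so thresholds are converted here).
nonwear_vote <- function(stats, spe, n_ep, epoch_len, window_min, step_min,
                         sd_threshold, range_threshold, axes_required) {
  w_ep <- round(window_min * 60 / epoch_len)
  s_ep <- max(1L, round(step_min * 60 / epoch_len))
  if (n_ep < w_ep) {
    warning("detect_nonwear: input shorter than one window; assuming full wear")
    return(rep(FALSE, n_ep))
  }
  # thresholds arrive in mg; raw-signal stats are in g
  in_g <- spe > 1L
  sd_thr <- if (in_g) sd_threshold / 1000 else sd_threshold
  rng_thr <- if (in_g) range_threshold / 1000 else range_threshold

  starts <- seq(1L, n_ep - w_ep + 1L, by = s_ep)
  if (tail(starts, 1) != n_ep - w_ep + 1L) starts <- c(starts, n_ep - w_ep + 1L)

  csum <- lapply(stats, function(s) cumsum(c(0, s$sum)))
  csumsq <- lapply(stats, function(s) cumsum(c(0, s$sumsq)))
  N <- w_ep * spe
  nonwear <- rep(FALSE, n_ep)
  for (st in starts) {
    en <- st + w_ep - 1L
    votes <- 0L
    for (a in seq_along(stats)) {
      tot <- csum[[a]][en + 1] - csum[[a]][st]
      tot2 <- csumsq[[a]][en + 1] - csumsq[[a]][st]
      v <- sqrt(pmax(0, (tot2 - tot^2 / N) / (N - 1)))
      rng <- max(stats[[a]]$max[st:en]) - min(stats[[a]]$min[st:en])
      if (v < sd_thr && rng < rng_thr) votes <- votes + 1L
    }
    if (votes >= axes_required) nonwear[st:en] <- TRUE
  }
  nonwear
}

#' Attach non-wear flags to an epoch series
#'
#' Recomputes the `wear` flag as not-non-wear AND not-abnormal.
#'
#' @param ep An [epoch_series()].
#' @param nonwear Logical vector as returned by [detect_nonwear()].
#' @return The updated [epoch_series()].
#' @export
flag_nonwear <- function(ep, nonwear) {
  stopifnot(inherits(ep, "epoch_series"), length(nonwear) == length(ep$enmo))
  epoch_series(ep$subject_id, ep$epoch_len, ep$start_time, ep$enmo,
               nonwear = as.logical(nonwear), abnormal = ep$abnormal,
               truth = ep$truth)
}
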