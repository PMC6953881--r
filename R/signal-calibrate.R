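# Autocalibration against local gravity.  During motionless wear the vector
# magnitude of a perfectly calibrated device equals exactly 1 g, whatever the
# orientation; offsets/gains are therefore estimable from still windows that
# cover enough orientations, without any external reference.

#' Autocalibrate a recording against local gravity
#'
#' Identifies still windows (non-overlapping windows whose per-axis sample SD
#' falls below `still_sd_threshold` on all three axes) and fits per-axis
#' offset and gain by iteratively reweighted least squares so that the
#' still-window mean vectors are pulled onto the unit-gravity sphere: at each
#' iteration the current calibrated vectors are projected to their closest
#' point on the sphere and each axis is regressed (weighted by closeness to
#' the sphere) on its projection, compounding the offset/gain estimates.
#'
#' If fewer than `min_windows` still windows are found, or the windows lack
#' orientation coverage (every axis must take both signs across the window
#' means, otherwise offset and gain are not separable on that axis), the
#' identity model is returned with `converged = FALSE` and the recording is
#' used as-is downstream.
#'
#' @param rec A [raw_recording()] of at least one hour.
#' @param still_sd_threshold Still-window criterion, mg (default 13).
#' @param window_len Still-window length, seconds (default 10).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the change in mean calibration error
#'   between iterations, mg.
#' @param min_windows Minimum number of still windows required.
#' @return A `calibration_model`: per-axis `offset` (g) and `gain`,
#'   `n_still_windows`, `pre_error`/`post_error` (mean absolute deviation of
#'   still-window magnitude from 1 g, in mg) and a `converged` flag.
#' @examples
#' rec <- simulate_still_recording(axis_offsets = c(0.1, -0.05, 0.02), seed = 3)
#' cal <- autocalibrate(rec)
#' round(cal$offset, 3)
#' @export
autocalibrate <- function(rec, still_sd_threshold = 13, window_len = 10,
                          max_iter = 50, tol = 0.1, min_windows = 10) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec_duration_s(rec) < 3600)
    stop_input("autocalibrate: recording must span at least one hour")
  spe <- max(2L, round(window_len * rec$sample_rate))
  n_win <- floor(n_samples(rec) / spe)
  idx <- seq_len(n_win * spe)
  g <- rep(seq_len(n_win), each = spe)

  thr_g <- still_sd_threshold / 1000
  win_stats <- function(v) {
    s <- as.numeric(tapply(v[idx], g, sum))
    s2 <- as.numeric(tapply(v[idx], g, function(u) sum(u^2)))
    m <- s / spe
    sdv <- sqrt(pmax(0, (s2 - s^2 / spe) / (spe - 1)))
    list(mean = m, sd = sdv)
  }
  sx <- win_stats(rec$x); sy <- win_stats(rec$y); sz <- win_stats(rec$z)
  still <- sx$sd < thr_g & sy$sd < thr_g & sz$sd < thr_g
  M <- cbind(sx$mean[still], sy$mean[still], sz$mean[still])

  identity_model <- function(pre, n) {
    structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                   n_still_windows = n, pre_error = pre, post_error = pre,
                   converged = FALSE),
              class = "calibration_model")
  }
  err_mg <- function(V) mean(abs(sqrt(rowSums(V^2)) - 1)) * 1000
  if (nrow(M) < min_windows)
    return(identity_model(if (nrow(M)) err_mg(M) else NA_real_, nrow(M)))
  # orientation coverage: each axis must change sign across still windows
  coverage <- all(apply(M, 2, function(v) min(v) < 0 && max(v) > 0))
  pre <- err_mg(M)
  if (!coverage) return(identity_model(pre, nrow(M)))

  off <- c(0, 0, 0); gain <- c(1, 1, 1)
  last_err <- pre
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    curr <- sweep(sweep(M, 2, off, "-"), 2, gain, "*")
    nrm <- sqrt(rowSums(curr^2))
    target <- curr / nrm
    w <- pmin(1 / pmax(abs(nrm - 1), 1e-3), 100)
    for (a in 1:3) {
      fit <- lm.wfit(cbind(1, curr[, a]), target[, a], w)
      b <- fit$coefficients[1]; slope <- fit$coefficients[2]
      if (!is.finite(slope) || slope <= 0) next
      gain[a] <- gain[a] * slope
      off[a] <- off[a] - b / gain[a]
    }
    curr <- sweep(sweep(M, 2, off, "-"), 2, gain, "*")
    e <- err_mg(curr)
    if (abs(last_err - e) < tol) { converged <- TRUE; last_err <- e; break }
    last_err <- e
  }
  post <- last_err
  if (post > pre) {  # fit made things worse: fall back to identity
    return(identity_model(pre, nrow(M)))
  }
  structure(list(offset = off, gain = gain, n_still_windows = nrow(M),
                 pre_error = pre, post_error = post, converged = converged),
            class = "calibration_model")
}

#' Identity calibration model
#' @return A `calibration_model` that leaves the signal unchanged.
#' @export
identity_calibration <- function() {
  structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                 n_still_windows = 0L, pre_error = NA_real_,
                 post_error = NA_real_, converged = TRUE),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> offset (g): %s | gain: %s\n  %d still windows, error %s -> %s mg, converged: %s\n",
    paste(sprintf("%+.4f", x$offset), collapse = " "),
    paste(sprintf("%.4f", x$gain), collapse = " "),
    x$n_still_windows,
    format(round(x$pre_error, 2)), format(round(x$post_error, 2)),
    x$converged))
  invisible(x)
}

#' Apply a calibration model to a raw recording
#'
#' Per axis: `calibrated = (measured - offset) * gain`.
#'
#' @param rec A [raw_recording()].
#' @param calib A `calibration_model` from [autocalibrate()].
#' @return The calibrated [raw_recording()].
#' @export
apply_calibration <- function(rec, calib) {
  stopifnot(inherits(rec, "raw_recording"), inherits(calib, "calibration_model"))
  rec$x <- (rec$x - calib$offset[1]) * calib$gain[1]
  rec$y <- (rec$y - calib$offset[2]) * calib$gain[2]
  rec$z <- (rec$z - calib$offset[3]) * calib$gain[3]
  rec
}
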