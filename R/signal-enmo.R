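# Abnormal-value screening and ENMO epoch summarisation.

#' Screen sustained abnormally high values
#'
#' Samples exceeding the device's dynamic range (default +/- 8 g) on any axis
#' are not compatible with human wrist movement.  They are flagged and
#' clipped to the range limit; the sample-level mask travels with the
#' recording and is propagated to epoch level by [compute_enmo()] (an epoch
#' is abnormal when more than half its samples are flagged).
#'
#' @param rec A [raw_recording()].
#' @param clip Dynamic range limit in g (> 0, default 8).
#' @return The recording with values clipped to `[-clip, clip]` and a logical
#'   element `abnormal` marking the flagged samples.
#' @export
screen_abnormal <- function(rec, clip = 8) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!is_number(clip) || clip <= 0) stop_config("clip", "must be > 0 (g)")
  mask <- abs(rec$x) > clip | abs(rec$y) > clip | abs(rec$z) > clip
  rec$x <- pmin(pmax(rec$x, -clip), clip)
  rec$y <- pmin(pmax(rec$y, -clip), clip)
  rec$z <- pmin(pmax(rec$z, -clip), clip)
  rec$abnormal <- mask
  rec
}

#' Compute epoch-averaged ENMO from a raw recording
#'
#' ENMO (Euclidean norm minus one) isolates activity-related acceleration
#' from the ever-present 1 g of gravity: per sample,
#' `sqrt(x^2 + y^2 + z^2) - 1` g.  Negative values -- which arise only from
#' noise or calibration error, since a motionless device reads exactly 1 g --
#' are truncated to zero by default, then samples are averaged over
#' fixed-length epochs and expressed in mg.
#'
#' @param rec A [raw_recording()], optionally already screened with
#'   [screen_abnormal()] (its sample mask is then carried to epoch level).
#' @param calib Optional `calibration_model` applied before the norm
#'   (`(v - offset) * gain` per axis).
#' @param epoch_len Epoch length in seconds (default 5).  Must match the
#'   sampling cadence to within one sample per epoch.
#' @param negatives `"truncate"` (default; the canonical definition) or
#'   `"absolute"` (take `|norm - 1|`, kept for sensitivity analysis against
#'   the alternative reading of the metric).
#' @return An [epoch_series()] in mg; the trailing partial epoch is dropped.
#' @examples
#' rec <- raw_recording("A", 10, Sys.time(), rep(0, 100), rep(0, 100), rep(1.15, 100))
#' compute_enmo(rec, epoch_len = 5)$enmo   # 150 mg in each epoch
#' @export
compute_enmo <- function(rec, calib = NULL, epoch_len = 5,
                         negatives = c("truncate", "absolute")) {
  stopifnot(inherits(rec, "raw_recording"))
  negatives <- match.arg(negatives)
  if (n_samples(rec) == 0) stop_input("compute_enmo: empty recording")
  if (!is.null(calib)) rec <- apply_calibration(rec, calib)
  spe <- round(epoch_len * rec$sample_rate)
  if (spe < 1 || abs(spe - epoch_len * rec$sample_rate) > 1)
    stop_input(sprintf(
      "compute_enmo: epoch_len %g s does not align with the %g Hz cadence within one sample",
      epoch_len, rec$sample_rate))
  n_ep <- floor(n_samples(rec) / spe)
  if (n_ep == 0) stop_input("compute_enmo: recording shorter than one epoch")
  idx <- seq_len(n_ep * spe)

  r <- sqrt(rec$x[idx]^2 + rec$y[idx]^2 + rec$z[idx]^2) - 1
  r <- if (negatives == "truncate") pmax(r, 0) else abs(r)
  enmo <- colMeans(matrix(r, spe, n_ep)) * 1000

  abnormal <- if (!is.null(rec$abnormal))
    colMeans(matrix(rec$abnormal[idx], spe, n_ep)) > 0.5
  else rep(FALSE, n_ep)

  epoch_series(rec$subject_id, epoch_len, rec$start_time, enmo,
               abnormal = abnormal, truth = rec$truth)
}
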