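# Core data containers.  Plain lists with a class attribute, a validating
# constructor and a print method; ground-truth annotations from the synthetic
# generators travel in the `truth` element.

#' Construct a raw tri-axial recording
#'
#' Container for one subject's raw wrist-accelerometer signal: three axes in
#' gravitational units (g) at a fixed sampling rate.  Axis convention follows
#' wrist devices: Y vertical, X horizontal right-left, Z horizontal
#' front-back.
#'
#' @param subject_id Character scalar.
#' @param sample_rate Sampling frequency in Hz (e.g. 85.7 for a GENEActiv-class
#'   device).
#' @param start_time `POSIXct` start of the recording.  Timestamps are treated
#'   as timezone-naive local clock time (stored as UTC); days are local
#'   calendar days.
#' @param x,y,z Numeric vectors of equal length, acceleration in g.
#' @param truth Optional list of generator ground truth (internal).
#' @return An object of class `raw_recording`.
#' @seealso [read_raw_csv()], [simulate_raw_recording()]
#' @export
raw_recording <- function(subject_id, sample_rate, start_time, x, y, z,
                          truth = NULL) {
  if (!is_number(sample_rate, min = 1e-9))
    stop_config("sample_rate", "must be a positive number (Hz)")
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop_input("raw_recording: axes x, y, z must have equal length")
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))))
    stop_input("raw_recording: axis values must be finite")
  start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(
    list(subject_id = as.character(subject_id), sample_rate = sample_rate,
         start_time = start_time,
         x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         truth = truth),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- length(x$x)
  cat(sprintf("<raw_recording> subject %s: %d samples at %g Hz (%.2f h), start %s\n",
              x$subject_id, n, x$sample_rate, n / x$sample_rate / 3600,
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

n_samples <- function(rec) length(rec$x)

rec_duration_s <- function(rec) n_samples(rec) / rec$sample_rate

#' Construct an epoch-level ENMO series
#'
#' Fixed-length epoch summaries of one recording: ENMO in mg plus wear and
#' abnormal flags.  `wear` is defined as not-non-wear AND not-abnormal.
#'
#' @param subject_id Character scalar.
#' @param epoch_len Epoch length in seconds (default 5).
#' @param start_time `POSIXct` timestamp of the first epoch.
#' @param enmo Numeric vector, mean ENMO per epoch in mg (non-negative).
#' @param nonwear Logical vector, epoch flagged as device-not-worn.
#' @param abnormal Logical vector, epoch dominated by clipped/abnormal samples.
#' @param truth Optional generator ground truth (internal).
#' @return An object of class `epoch_series` with elements `enmo`, `wear`,
#'   `nonwear`, `abnormal` (all equal length).
#' @export
epoch_series <- function(subject_id, epoch_len = 5, start_time, enmo,
                         nonwear = NULL, abnormal = NULL, truth = NULL) {
  if (!is_number(epoch_len, min = 1e-9))
    stop_config("epoch_len", "must be a positive number of seconds")
  n <- length(enmo)
  nonwear <- nonwear %||% rep(FALSE, n)
  abnormal <- abnormal %||% rep(FALSE, n)
  if (length(nonwear) != n || length(abnormal) != n)
    stop_input("epoch_series: enmo, nonwear, abnormal must have equal length")
  if (n > 0 && any(enmo < 0, na.rm = TRUE))
    stop_input("epoch_series: enmo must be non-negative (mg)")
  structure(
    list(subject_id = as.character(subject_id), epoch_len = epoch_len,
         start_time = as.POSIXct(start_time, tz = "UTC"),
         enmo = as.numeric(enmo),
         nonwear = as.logical(nonwear), abnormal = as.logical(abnormal),
         wear = !nonwear & !abnormal,
         truth = truth),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$enmo)
  cat(sprintf(
    "<epoch_series> subject %s: %d x %g-s epochs (%.2f h), wear %.1f%%, start %s\n",
    x$subject_id, n, x$epoch_len, n * x$epoch_len / 3600,
    if (n) 100 * mean(x$wear) else NA_real_,
    format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

epoch_timestamps <- function(ep) {
  ep$start_time + (seq_along(ep$enmo) - 1) * ep$epoch_len
}

#' Construct a balanced subjects-by-days construct matrix
#'
#' The replicate structure the reliability analysis runs on: one physical
#' activity construct, one row per subject, one column per retained day.
#'
#' @param construct One of `"overall"` (mean ENMO, mg), `"lpa"` (light-activity
#'   minutes) or `"mvpa"` (bouted MVPA minutes) -- or any other label for
#'   ad-hoc use.
#' @param values Numeric matrix, subjects x days, no missing cells.
#' @param subject_ids Character vector, one per row.
#' @param dates Optional `Date` vector, one per column (day columns may hold
#'   different calendar dates per subject after valid-day selection; these are
#'   the first subject's, kept for labelling only).
#' @param day_of_week Optional integer vector (1 = Monday .. 7 = Sunday), one
#'   per column.
#' @param truth Optional list of generator ground truth, e.g. `icc_true`.
#' @return An object of class `construct_matrix`.
#' @export
construct_matrix <- function(construct, values, subject_ids = NULL,
                             dates = NULL, day_of_week = NULL, truth = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1) stop_config("n_subjects", "need at least 1 subject")
  if (ncol(values) < 2) stop_config("n_days", "need at least 2 days")
  if (any(!is.finite(values)))
    stop_input("construct_matrix: values must be complete and finite")
  subject_ids <- subject_ids %||% rownames(values) %||%
    sprintf("S%04d", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  structure(
    list(construct = construct, values = values,
         subject_ids = as.character(subject_ids),
         dates = dates, day_of_week = day_of_week, truth = truth),
    class = "construct_matrix"
  )
}

#' @export
print.construct_matrix <- function(x, ...) {
  cat(sprintf("<construct_matrix> %s: %d subjects x %d days\n",
              x$construct, nrow(x$values), ncol(x$values)))
  if (!is.null(x$truth$icc_true))
    cat(sprintf("  ground-truth ICC %.4f\n", x$truth$icc_true))
  invisible(x)
}

#' @export
as.matrix.construct_matrix <- function(x, ...) x$values

#' Long-format view of a construct matrix
#'
#' @param m A [construct_matrix()].
#' @return A data.frame with columns `subject_id`, `day_index`, `date`,
#'   `day_of_week`, `value`.
#' @export
construct_long <- function(m) {
  stopifnot(inherits(m, "construct_matrix"))
  k <- ncol(m$values)
  data.frame(
    subject_id = rep(m$subject_ids, times = k),
    day_index = rep(seq_len(k), each = nrow(m$values)),
    date = if (!is.null(m$dates)) rep(as.Date(m$dates), each = nrow(m$values))
           else as.Date(NA),
    day_of_week = if (!is.null(m$day_of_week)) rep(m$day_of_week, each = nrow(m$values))
                  else NA_integer_,
    value = as.vector(m$values),
    stringsAsFactors = FALSE
  )
}
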