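# Plain-text interchange formats.  All timestamps are written as ISO-8601
# local clock time without a zone designator and read back as UTC-naive.

ts_fmt <- "%Y-%m-%dT%H:%M:%OS"

fmt_ts <- function(t, digits = 3) {
  op <- options(digits.secs = digits); on.exit(options(op))
  format(t, ts_fmt, tz = "UTC")
}

#' Write / read a raw recording as CSV
#'
#' Columns: `timestamp_iso8601`, `x_g`, `y_g`, `z_g`.  The sampling rate is
#' recovered on read from the median timestamp increment.  A converter from
#' proprietary device binaries is deliberately not included; any reader that
#' can produce this four-column layout (e.g. an export from the vendor
#' software) plugs in here.
#'
#' @param rec A [raw_recording()].
#' @param path Output/input file path.
#' @param subject_id Subject label on read (defaults to the file stem).
#' @return `read_raw_csv()` returns a [raw_recording()];
#'   `write_raw_csv()` returns `path` invisibly.
#' @export
write_raw_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  ts <- rec$start_time + (seq_len(n_samples(rec)) - 1) / rec$sample_rate
  df <- data.frame(timestamp_iso8601 = fmt_ts(ts),
                   x_g = rec$x, y_g = rec$y, z_g = rec$z)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raw_csv
#' @export
read_raw_csv <- function(path, subject_id = NULL) {
  df <- read_checked_csv(path, c("timestamp_iso8601", "x_g", "y_g", "z_g"))
  ts <- as.POSIXct(df$timestamp_iso8601, format = ts_fmt, tz = "UTC")
  if (anyNA(ts)) stop_input(sprintf(
    "read_raw_csv: unparseable timestamp near line %d of %s",
    which(is.na(ts))[1] + 1L, path))
  dt <- median(diff(as.numeric(ts)))
  rate <- if (is.finite(dt) && dt > 0) 1 / dt else
    stop_input("read_raw_csv: cannot infer sampling rate from timestamps")
  raw_recording(subject_id %||% sub("\\.csv$", "", basename(path)),
                rate, ts[1], df$x_g, df$y_g, df$z_g)
}

#' Write / read an epoch series as CSV
#'
#' Columns: `timestamp`, `enmo_mg`, `wear`, `abnormal` (plus `nonwear`,
#' kept so wear can be reconstituted exactly).
#'
#' @param ep An [epoch_series()].
#' @param path File path.
#' @param subject_id Subject label on read.
#' @return `read_epoch_csv()` returns an [epoch_series()].
#' @export
write_epoch_csv <- function(ep, path) {
  stopifnot(inherits(ep, "epoch_series"))
  df <- data.frame(timestamp = fmt_ts(epoch_timestamps(ep), digits = 0),
                   enmo_mg = round(ep$enmo, 4),
                   wear = ep$wear, nonwear = ep$nonwear, abnormal = ep$abnormal)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epoch_csv
#' @export
read_epoch_csv <- function(path, subject_id = NULL) {
  df <- read_checked_csv(path, c("timestamp", "enmo_mg", "nonwear", "abnormal"))
  ts <- as.POSIXct(df$timestamp, format = ts_fmt, tz = "UTC")
  if (anyNA(ts)) stop_input(sprintf(
    "read_epoch_csv: unparseable timestamp near line %d of %s",
    which(is.na(ts))[1] + 1L, path))
  epoch_len <- if (nrow(df) > 1) median(diff(as.numeric(ts))) else 5
  epoch_series(subject_id %||% sub("\\.csv$", "", basename(path)),
               epoch_len, ts[1], df$enmo_mg,
               nonwear = df$nonwear, abnormal = df$abnormal)
}

#' Write / read stacked day summaries as CSV
#'
#' Columns: `subject_id`, `date`, `dow`, `wear_hours`, `overall_pa_mg`,
#' `lpa_min`, `mvpa_bouted_min`, `valid`.
#'
#' @param days Day-summary data.frame from [summarize_day()].
#' @param path File path.
#' @return `read_day_summary_csv()` returns the data.frame.
#' @export
write_day_summary_csv <- function(days, path) {
  cols <- c("subject_id", "date", "dow", "wear_hours", "overall_pa_mg",
            "lpa_min", "mvpa_bouted_min", "valid")
  df <- days[, cols]
  for (cc in c("wear_hours", "overall_pa_mg", "lpa_min", "mvpa_bouted_min"))
    df[[cc]] <- round(df[[cc]], 4)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_day_summary_csv
#' @export
read_day_summary_csv <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "date", "dow", "wear_hours",
                                 "overall_pa_mg", "lpa_min",
                                 "mvpa_bouted_min", "valid"))
  df$subject_id <- as.character(df$subject_id)
  df$date <- as.Date(df$date)
  df$valid <- as.logical(df$valid)
  df
}

#' Write / read a construct matrix as long CSV
#'
#' Columns: `subject_id`, `day_index`, `date`, `value` (one construct per
#' file; the construct name is taken from the file on read unless given).
#'
#' @param m A [construct_matrix()].
#' @param path File path.
#' @param construct Construct label on read.
#' @return `read_construct_matrix_csv()` returns a [construct_matrix()].
#' @export
write_construct_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "construct_matrix"))
  long <- construct_long(m)
  long$value <- round(long$value, 6)
  long$day_of_week <- NULL
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_construct_matrix_csv
#' @export
read_construct_matrix_csv <- function(path, construct = NULL) {
  df <- read_checked_csv(path, c("subject_id", "day_index", "value"))
  ids <- unique(df$subject_id)
  ks <- sort(unique(df$day_index))
  v <- matrix(NA_real_, length(ids), length(ks),
              dimnames = list(ids, ks))
  v[cbind(match(df$subject_id, ids), match(df$day_index, ks))] <- df$value
  if (any(is.na(v)))
    stop_input("read_construct_matrix_csv: unbalanced matrix (missing cells)")
  dates <- if ("date" %in% names(df))
    as.Date(df$date[match(ks, df$day_index)]) else NULL
  dow <- if (!is.null(dates) && !anyNA(dates)) iso_dow(dates) else NULL
  construct_matrix(construct %||% sub("\\.csv$", "", basename(path)),
                   v, subject_ids = as.character(ids),
                   dates = dates, day_of_week = dow)
}

# read.csv with a schema check and parse errors that name the file.
read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_input(
                   sprintf("malformed CSV %s: %s", path, conditionMessage(e))))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_input(sprintf("%s: missing required column(s) %s",
                       path, paste(missing, collapse = ", ")))
  df
}
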