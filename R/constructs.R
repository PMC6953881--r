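# From epochs to daily physical-activity constructs: intensity
# classification, MVPA bout detection, calendar-day summaries and the
# analytical-sample filter.

#' Classify wear epochs into intensity bands
#'
#' MVPA is strictly above the `mvpa_threshold` (default 100 mg); LPA is the
#' closed band `[lpa_low, mvpa_threshold]` (default 50--100 mg, both
#' boundaries inclusive, so 100 mg itself is light); anything below is
#' sedentary.  Non-wear epochs are left unlabelled (`NA`).
#'
#' @param ep An [epoch_series()].
#' @param lpa_low Lower LPA boundary, mg.
#' @param mvpa_threshold MVPA threshold, mg (must exceed `lpa_low`).
#' @return A character vector (`"sedentary"`, `"light"`, `"mvpa"`, or `NA`
#'   for non-wear), one per epoch.
#' @export
classify_epochs <- function(ep, lpa_low = 50, mvpa_threshold = 100) {
  stopifnot(inherits(ep, "epoch_series"))
  if (!is_number(lpa_low) || !is_number(mvpa_threshold) ||
      lpa_low <= 0 || lpa_low >= mvpa_threshold)
    stop_config("lpa_low/mvpa_threshold", "need 0 < lpa_low < mvpa_threshold (mg)")
  lab <- rep(NA_character_, length(ep$enmo))
  w <- ep$wear
  lab[w & ep$enmo > mvpa_threshold] <- "mvpa"
  lab[w & ep$enmo >= lpa_low & ep$enmo <= mvpa_threshold] <- "light"
  lab[w & ep$enmo < lpa_low] <- "sedentary"
  lab
}

#' Detect bouts of moderate-to-vigorous activity
#'
#' A bout is a sustained period of at least `min_bout` minutes in which at
#' least `min_fraction` of epochs are MVPA.  The criterion alone does not
#' pin down an algorithm, so the scan is fully specified here: a greedy
#' left-to-right pass where a candidate bout starts at an MVPA epoch and is
#' the longest window starting there that (a) spans at least `min_bout`
#' minutes, (b) has an MVPA fraction of at least `min_fraction`, (c) ends on
#' an MVPA epoch, and (d) contains no run of consecutive non-MVPA epochs
#' longer than `(1 - min_fraction) * min_bout` minutes.  Accepted bouts do
#' not overlap; the scan resumes after each accepted bout.  Unlabelled
#' (non-wear) epochs break bouts unconditionally.
#'
#' @param labels Character labels from [classify_epochs()] (`NA` = non-wear).
#' @param epoch_len Epoch length, seconds.
#' @param min_bout Minimum bout duration, minutes (default 10).
#' @param min_fraction Minimum MVPA fraction within a bout (default 0.8).
#' @return A data.frame of accepted bouts with columns `start_epoch`,
#'   `end_epoch` (inclusive indices), `n_epochs`, `duration_min`,
#'   `fraction_above`.
#' @examples
#' lab <- rep("mvpa", 120)                      # 10 min of 5-s epochs
#' detect_mvpa_bouts(lab, epoch_len = 5)        # one 10-min bout
#' @export
detect_mvpa_bouts <- function(labels, epoch_len = 5, min_bout = 10,
                              min_fraction = 0.8) {
  if (!is_number(min_bout) || min_bout <= 0)
    stop_config("min_bout", "must be > 0 (minutes)")
  if (!is_number(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stop_config("min_fraction", "must be in (0, 1]")
  n <- length(labels)
  is_m <- !is.na(labels) & labels == "mvpa"
  is_break <- is.na(labels)                    # non-wear breaks unconditionally
  # guard against floating-point shortfall, e.g. (1 - 0.8) * 600 / 5 = 23.99..
  min_ep <- ceiling(min_bout * 60 / epoch_len - 1e-9)
  max_gap <- floor((1 - min_fraction) * min_bout * 60 / epoch_len + 1e-9)

  if (n == 0) {
    return(data.frame(start_epoch = integer(0), end_epoch = integer(0),
                      n_epochs = integer(0), duration_min = numeric(0),
                      fraction_above = numeric(0)))
  }

  # run length of consecutive non-MVPA epochs ending at each position
  # (Inf at break epochs so condition (d) can never pass across them)
  cat3 <- ifelse(is_break, 2L, ifelse(is_m, 0L, 1L))
  rl <- rle(cat3)
  vrep <- rep(rl$values, rl$lengths)
  r <- sequence(rl$lengths)
  r[vrep == 0L] <- 0
  r <- as.numeric(r)
  r[vrep == 2L] <- Inf
  cm <- cumsum(is_m)

  # first position at or after j where the run length breaks condition (d)
  bad <- r > max_gap
  nxt_bad <- rep(n + 1L, n)
  nxt_bad[bad] <- which(bad)
  nxt_bad <- rev(cummin(rev(nxt_bad)))

  mpos <- which(is_m)
  out <- list()
  p <- 1L
  while (p <= length(mpos)) {
    s <- mpos[p]
    lim <- nxt_bad[s] - 1L   # scan cannot extend past an over-long gap
    e_cand <- seq.int(s, lim)
    len <- e_cand - s + 1L
    frac <- (cm[e_cand] - cm[s] + 1L) / len
    ok <- is_m[e_cand] & len >= min_ep & frac >= min_fraction
    if (any(ok)) {
      e <- e_cand[max(which(ok))]
      out[[length(out) + 1L]] <- c(s, e, e - s + 1L,
                                   (cm[e] - cm[s] + 1L) / (e - s + 1L))
      while (p <= length(mpos) && mpos[p] <= e) p <- p + 1L
    } else {
      p <- p + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start_epoch = integer(0), end_epoch = integer(0),
                      n_epochs = integer(0), duration_min = numeric(0),
                      fraction_above = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start_epoch = as.integer(m[, 1]), end_epoch = as.integer(m[, 2]),
             n_epochs = as.integer(m[, 3]),
             duration_min = m[, 3] * epoch_len / 60,
             fraction_above = m[, 4])
}

#' Summarise an epoch series into calendar-day constructs
#'
#' Splits the series into local calendar days (midnight to midnight; partial
#' first/last days are excluded) and computes, per day: wear hours, overall
#' activity (mean ENMO over wear epochs, mg -- no imputation of non-wear
#' time), light-activity minutes, bouted MVPA minutes (every epoch inside an
#' accepted bout counts, including sub-threshold interruptions), plus
#' unbouted MVPA and sedentary minutes for accounting.  A day is valid when
#' its wear time reaches `min_wear_hours` (default 16 h).
#'
#' @param ep An [epoch_series()].
#' @param labels Intensity labels from [classify_epochs()]; computed with
#'   defaults if omitted.
#' @param bouts Bout table from [detect_mvpa_bouts()]; computed with defaults
#'   if omitted.
#' @param min_wear_hours Valid-day criterion, hours.
#' @return A data.frame with one row per complete calendar day: `subject_id`,
#'   `date`, `dow` (1 = Monday), `wear_hours`, `overall_pa_mg` (`NA` when a
#'   day has no wear), `lpa_min`, `mvpa_bouted_min`, `mvpa_unbouted_min`,
#'   `sedentary_min`, `valid`.
#' @export
summarize_day <- function(ep, labels = NULL, bouts = NULL,
                          min_wear_hours = 16) {
  stopifnot(inherits(ep, "epoch_series"))
  if (!is_number(min_wear_hours) || min_wear_hours <= 0 || min_wear_hours > 24)
    stop_config("min_wear_hours", "must be in (0, 24]")
  labels <- labels %||% classify_epochs(ep)
  bouts <- bouts %||% detect_mvpa_bouts(labels, epoch_len = ep$epoch_len)
  n <- length(ep$enmo)
  ts <- epoch_timestamps(ep)
  day <- as.Date(ts, tz = "UTC")
  epd <- 86400 / ep$epoch_len

  in_bout <- rep(FALSE, n)
  if (nrow(bouts)) for (i in seq_len(nrow(bouts)))
    in_bout[bouts$start_epoch[i]:bouts$end_epoch[i]] <- TRUE

  tab <- table(day)
  days <- as.Date(names(tab)[tab == epd])
  if (!length(days))
    stop_input("summarize_day: series does not cover one complete calendar day")

  rows <- lapply(seq_along(days), function(di) {
    d <- days[di]
    i <- which(day == d)
    w <- ep$wear[i]
    lab <- labels[i]
    wear_hours <- sum(w) * ep$epoch_len / 3600
    to_min <- ep$epoch_len / 60
    data.frame(
      subject_id = ep$subject_id, date = d, dow = iso_dow(d),
      wear_hours = wear_hours,
      overall_pa_mg = if (any(w)) mean(ep$enmo[i][w]) else NA_real_,
      lpa_min = sum(lab == "light", na.rm = TRUE) * to_min,
      mvpa_bouted_min = sum(in_bout[i] & w) * to_min,
      mvpa_unbouted_min = sum(lab == "mvpa", na.rm = TRUE) * to_min,
      sedentary_min = sum(lab == "sedentary", na.rm = TRUE) * to_min,
      valid = wear_hours >= min_wear_hours,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Select the analytical sample and build balanced construct matrices
#'
#' Keeps subjects contributing at least `min_valid_days` valid days and, for
#' each, retains the first `k_keep` valid days in chronological order --
#' yielding one balanced subjects-by-days matrix per construct (overall
#' activity, LPA minutes, bouted MVPA minutes).
#'
#' @param days Day-summary data.frame from [summarize_day()] (rows from many
#'   subjects stacked).
#' @param min_valid_days Minimum valid days per subject (default 6).
#' @param k_keep Days retained per kept subject (default 6; at most
#'   `min_valid_days`).
#' @return A list with `matrices` (named list of [construct_matrix()] for
#'   `overall`, `lpa`, `mvpa`), `n_included`, `n_excluded`, and
#'   `included_ids`.
#' @export
select_analytical_sample <- function(days, min_valid_days = 6, k_keep = 6) {
  if (!is_count(min_valid_days, min = 2))
    stop_config("min_valid_days", "must be an integer >= 2")
  if (!is_count(k_keep, min = 2) || k_keep > min_valid_days)
    stop_config("k_keep", "must be an integer in 2..min_valid_days")
  need <- c("subject_id", "date", "dow", "overall_pa_mg", "lpa_min",
            "mvpa_bouted_min", "valid")
  if (!all(need %in% names(days)))
    stop_input(paste("select_analytical_sample: day summary lacks columns:",
                     paste(setdiff(need, names(days)), collapse = ", ")))

  valid <- days[days$valid & !is.na(days$overall_pa_mg), , drop = FALSE]
  counts <- table(valid$subject_id)
  keep_ids <- names(counts)[counts >= min_valid_days]
  all_ids <- unique(days$subject_id)
  if (!length(keep_ids))
    stop_input(sprintf(
      "select_analytical_sample: no subject has >= %d valid days", min_valid_days))

  first_k <- lapply(keep_ids, function(id) {
    d <- valid[valid$subject_id == id, , drop = FALSE]
    d[order(d$date), , drop = FALSE][seq_len(k_keep), , drop = FALSE]
  })
  grab <- function(col) {
    t(vapply(first_k, function(d) d[[col]], numeric(k_keep)))
  }
  dow1 <- first_k[[1]]$dow
  dates1 <- first_k[[1]]$date
  mats <- list(
    overall = construct_matrix("overall", grab("overall_pa_mg"),
                               subject_ids = keep_ids, dates = dates1,
                               day_of_week = dow1),
    lpa = construct_matrix("lpa", grab("lpa_min"), subject_ids = keep_ids,
                           dates = dates1, day_of_week = dow1),
    mvpa = construct_matrix("mvpa", grab("mvpa_bouted_min"),
                            subject_ids = keep_ids, dates = dates1,
                            day_of_week = dow1)
  )
  list(matrices = mats, n_included = length(keep_ids),
       n_excluded = length(all_ids) - length(keep_ids),
       included_ids = keep_ids)
}
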