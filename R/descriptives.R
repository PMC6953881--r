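# Day-of-week and weekday/weekend descriptives with rank-based tests.
# Subject-days are pooled as independent observations (no within-subject
# clustering adjustment), which is the simple design these medians are
# conventionally reported under; a documented limitation.

construct_column <- function(construct) {
  switch(construct,
         overall = "overall_pa_mg",
         lpa = "lpa_min",
         mvpa = "mvpa_bouted_min",
         stop_config("construct", "must be one of overall, lpa, mvpa"))
}

#' Day-of-week and weekday/weekend medians with rank tests
#'
#' Computes, over all valid subject-days, the median of one construct per
#' day of week (Monday..Sunday), a Kruskal-Wallis test across the seven day
#' groups (its statistic is chi-squared distributed under the null), and the
#' weekday (Mon-Fri) vs weekend (Sat-Sun) medians with a Wilcoxon rank-sum
#' test.
#'
#' @param days Either a day-summary data.frame from [summarize_day()] (then
#'   `construct` picks the column) or any data.frame with columns `value` and
#'   `dow` (and optionally `valid`).
#' @param construct `"overall"`, `"lpa"` or `"mvpa"` (ignored when a `value`
#'   column is supplied).
#' @param group Label carried into the output.
#' @return A list of class `dow_summary`: `medians` and `n_obs` (length-7,
#'   Monday first; empty categories are `NA` with a warning),
#'   `weekday_median`, `weekend_median`, `p_dow`, `p_wkend`, `degenerate`
#'   flag (all values tied -- tests skipped).
#' @export
dow_medians <- function(days, construct = "overall", group = "all") {
  if (!is.data.frame(days)) stop_input("dow_medians: `days` must be a data.frame")
  if ("value" %in% names(days)) {
    val <- days$value
  } else {
    col <- construct_column(construct)
    if (!col %in% names(days))
      stop_input(sprintf("dow_medians: column `%s` not found", col))
    val <- days[[col]]
  }
  if (!"dow" %in% names(days)) {
    if ("day_of_week" %in% names(days)) days$dow <- days$day_of_week
    else stop_input("dow_medians: need a `dow` (or `day_of_week`) column")
  }
  keep <- !is.na(val)
  if ("valid" %in% names(days)) keep <- keep & days$valid
  val <- val[keep]
  dow <- as.integer(days$dow[keep])
  if (!length(val)) stop_input("dow_medians: no valid observations")

  medians <- n_obs <- rep(NA_real_, 7)
  for (d in 1:7) {
    v <- val[dow == d]
    n_obs[d] <- length(v)
    if (length(v)) medians[d] <- median(v)
  }
  names(medians) <- names(n_obs) <-
    c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  empty <- n_obs == 0
  if (any(empty))
    warning("dow_medians: no valid days for ",
            paste(names(n_obs)[empty], collapse = ", "),
            "; medians marked missing, tests skipped for those categories")

  wkend <- is_weekend(dow)
  weekday_median <- if (any(!wkend)) median(val[!wkend]) else NA_real_
  weekend_median <- if (any(wkend)) median(val[wkend]) else NA_real_

  degenerate <- length(unique(val)) < 2
  p_dow <- p_wkend <- NA_real_
  if (!degenerate) {
    present <- unique(dow)
    if (length(present) >= 2)
      p_dow <- suppressWarnings(kruskal.test(val, factor(dow))$p.value)
    if (any(wkend) && any(!wkend))
      p_wkend <- suppressWarnings(
        wilcox.test(val[!wkend], val[wkend], exact = FALSE)$p.value)
  } else {
    warning("dow_medians: all values identical; rank tests are degenerate")
  }

  structure(list(construct = construct, group = group,
                 medians = medians, n_obs = n_obs,
                 weekday_median = weekday_median,
                 weekend_median = weekend_median,
                 p_dow = p_dow, p_wkend = p_wkend,
                 degenerate = degenerate),
            class = "dow_summary")
}

#' @export
print.dow_summary <- function(x, ...) {
  cat(sprintf("<dow_summary> %s (%s)\n", x$construct, x$group))
  print(round(rbind(median = x$medians, n = x$n_obs), 2))
  cat(sprintf("  weekday %.2f vs weekend %.2f;  p(dow) = %s, p(wkend) = %s%s\n",
              x$weekday_median, x$weekend_median,
              format.pval(x$p_dow, digits = 3),
              format.pval(x$p_wkend, digits = 3),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Flat table of day-of-week medians
#'
#' @param x A `dow_summary` (or list of them).
#' @return A data.frame with columns `group`, `construct`, `dow`, `median`,
#'   `n` -- the serialisable layout of the day-of-week summary.
#' @export
dow_table <- function(x) {
  if (inherits(x, "dow_summary")) x <- list(x)
  do.call(rbind, lapply(x, function(s) {
    data.frame(group = s$group, construct = s$construct,
               dow = 1:7, day = names(s$medians),
               median = unname(s$medians), n = unname(s$n_obs),
               stringsAsFactors = FALSE)
  }))
}
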