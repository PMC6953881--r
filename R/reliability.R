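# Single-day reliability and the Spearman-Brown step-up: how much of the
# day-to-day variability is true between-subject signal, and how many days
# must be averaged before the mean represents habitual behaviour.

#' Single-day intraclass correlation (one-way random effects)
#'
#' Treats days as exchangeable replicates of each subject's habitual level
#' and estimates the single-measurement ICC from the one-way ANOVA mean
#' squares: with `MSB` the between-subject and `MSW` the within-subject mean
#' square over `k` days,
#' `ICC = (MSB - MSW) / (MSB + (k - 1) * MSW)`.
#' This is the proportion of single-day variance attributable to stable
#' between-subject differences, i.e. the reliability of one monitoring day.
#' Negative estimates (possible by sampling noise when the true ICC is near
#' 0) are returned as-is but flagged.
#'
#' @param m A [construct_matrix()] or a complete numeric matrix
#'   (subjects x days, n >= 2, k >= 2).
#' @return A list of class `icc_result`: `icc1`, `msb`, `msw`, `n_subjects`,
#'   `k_days`, `negative` flag.
#' @export
icc_single_day <- function(m) {
  v <- if (inherits(m, "construct_matrix")) m$values else as.matrix(m)
  if (nrow(v) < 2 || ncol(v) < 2)
    stop_input("icc_single_day: need at least 2 subjects and 2 days")
  if (any(!is.finite(v)))
    stop_input("icc_single_day: matrix must be complete (balanced, no NA)")
  n <- nrow(v); k <- ncol(v)
  if (stats::var(as.vector(v)) == 0)
    stop_input("icc_single_day: constant matrix has no variance to partition")
  rm_ <- rowMeans(v)
  gm <- mean(v)
  msb <- k * sum((rm_ - gm)^2) / (n - 1)
  msw <- sum((v - rm_)^2) / (n * (k - 1))
  icc1 <- (msb - msw) / (msb + (k - 1) * msw)
  structure(list(icc1 = icc1, msb = msb, msw = msw, n_subjects = n,
                 k_days = k, negative = icc1 < 0),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(1) = %.4f  (MSB %.4g, MSW %.4g; n = %d, k = %d)%s\n",
              x$icc1, x$msb, x$msw, x$n_subjects, x$k_days,
              if (x$negative) "  [negative estimate]" else ""))
  invisible(x)
}

#' Spearman-Brown prophecy: reliability of a k-day average
#'
#' `r_k = k * r1 / (1 + (k - 1) * r1)` -- the reliability of the mean of `k`
#' exchangeable days given single-day reliability `r1`.
#'
#' @param r1 Single-day reliability in (0, 1]; values <= 0 are a domain error
#'   (averaging more days of pure noise predicts nothing).
#' @param k Number of days (integer-valued, >= 1; vectorised).
#' @return `r_k`, same length as `k`.
#' @examples
#' spearman_brown(0.44, 6)   # 0.825
#' spearman_brown(0.54, 1:6)
#' @export
spearman_brown <- function(r1, k) {
  if (!is_number(r1) || r1 <= 0)
    stop_domain("spearman_brown: r1 must be in (0, 1]; the prophecy is undefined for r1 <= 0")
  if (r1 > 1) stop_domain("spearman_brown: r1 cannot exceed 1")
  if (any(k < 1) || any(k != floor(k)))
    stop_domain("spearman_brown: k must be a positive integer")
  k * r1 / (1 + (k - 1) * r1)
}

#' Minimum number of monitoring days for a target reliability
#'
#' Inverts the Spearman-Brown prophecy: the smallest integer `k` whose
#' stepped-up reliability exceeds (`strict = TRUE`, the default, matching the
#' conventional "> 0.70" reading) or reaches (`strict = FALSE`) the target.
#' The closed form `k = target * (1 - r1) / (r1 * (1 - target))` is rounded
#' up and then verified by direct evaluation, which also settles the boundary
#' cases the ceiling cannot.
#'
#' @param r1 Single-day reliability in (0, 1).
#' @param target Target reliability in (0, 1), default 0.70.
#' @param strict Require strictly greater than the target?
#' @return Integer `k >= 1`.
#' @examples
#' min_days(0.44, 0.70)   # 3
#' min_days(0.54, 0.70)   # 2
#' @export
min_days <- function(r1, target = 0.70, strict = TRUE) {
  if (!is_number(r1) || r1 <= 0)
    stop_domain("min_days: r1 must be in (0, 1)")
  if (!is_number(target) || target <= 0 || target >= 1)
    stop_config("target", "must be in (0, 1)")
  if (r1 >= 1) return(1L)
  hit <- function(k) {
    rk <- spearman_brown(r1, k)
    if (strict) rk > target else rk >= target
  }
  k <- max(1, ceiling(target * (1 - r1) / (r1 * (1 - target))))
  while (!hit(k)) k <- k + 1
  while (k > 1 && hit(k - 1)) k <- k - 1
  as.integer(k)
}

#' Reliability report over constructs (and groups)
#'
#' For each balanced construct matrix: the single-day ICC, the Spearman-Brown
#' curve for `k = 1..K` days, and the minimum days needed to exceed the
#' target reliability.  Matrices with a negative ICC estimate are flagged and
#' excluded from the prophecy (curve and minimum days `NA`) rather than
#' clamped.
#'
#' @param matrices A single [construct_matrix()] or a (possibly nested, one
#'   level: group -> construct) named list of them.
#' @param K Maximum number of days on the curve (default 6).
#' @param target Target reliability (default 0.70).
#' @param strict Strict inequality at the target (default `TRUE`).
#' @return A list of class `reliability_report` with
#'   \describe{
#'     \item{`results`}{one record per group x construct: `icc1`, `msb`,
#'       `msw`, `r_by_days` (named vector `k = 1..K`), `min_days`,
#'       `min_days_attainable`, counts and flags;}
#'     \item{`curves`}{a flat data.frame (`group`, `construct`, `k`,
#'       `reliability`, `reliability_2dp`) mirroring a reliability-by-days
#'       figure, coefficients also given rounded half-away-from-zero to two
#'       decimals as conventionally printed;}
#'     \item{`target`, `K`}{the settings used.}
#'   }
#' @export
reliability_report <- function(matrices, K = 6, target = 0.70, strict = TRUE) {
  if (!is_count(K, min = 1)) stop_config("K", "must be a positive integer")
  if (inherits(matrices, "construct_matrix"))
    matrices <- list(all = list(overall = matrices))
  if (all(vapply(matrices, inherits, logical(1), "construct_matrix")))
    matrices <- list(all = matrices)

  results <- list()
  curves <- list()
  for (g in names(matrices)) {
    for (cn in names(matrices[[g]])) {
      m <- matrices[[g]][[cn]]
      ic <- icc_single_day(m)
      if (ic$negative || ic$icc1 == 0) {
        r_by_days <- c(ic$icc1, rep(NA_real_, K - 1))
        md <- NA_integer_; attainable <- FALSE
      } else {
        r1 <- min(ic$icc1, 1)
        r_by_days <- spearman_brown(r1, seq_len(K))
        md <- min_days(r1, target, strict)
        attainable <- md <= K
      }
      names(r_by_days) <- seq_len(K)
      results[[paste(g, cn, sep = ".")]] <- list(
        group = g, construct = cn, icc1 = ic$icc1, msb = ic$msb, msw = ic$msw,
        n_subjects = ic$n_subjects, k_days = ic$k_days,
        negative = ic$negative, r_by_days = r_by_days,
        min_days = md, min_days_attainable = attainable,
        target = target)
      curves[[paste(g, cn, sep = ".")]] <- data.frame(
        group = g, construct = cn, k = seq_len(K), reliability = r_by_days,
        reliability_2dp = round_half_up(r_by_days, 2),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(results = results,
                 curves = do.call(rbind, c(curves, list(make.row.names = FALSE))),
                 target = target, K = K),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> target > %.2f, K = %d\n", x$target, x$K))
  for (r in x$results) {
    cat(sprintf("  %s/%s: ICC(1) = %.3f -> %d-day r = %s; min days = %s%s\n",
                r$group, r$construct, r$icc1, x$K,
                format(round_half_up(r$r_by_days[x$K], 2)),
                if (is.na(r$min_days)) "NA" else r$min_days,
                if (r$negative) " [negative ICC, prophecy skipped]" else ""))
  }
  invisible(x)
}

#' Plot reliability-by-days curves
#'
#' @param x A `reliability_report`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.reliability_report <- function(x, ...) {
  ks <- seq_len(x$K)
  mat <- vapply(x$results, function(r) unname(r$r_by_days), numeric(x$K))
  graphics::matplot(ks, mat, type = "b", pch = 19, lty = 1,
                    xlab = "Measurement days", ylab = "Reliability coefficient",
                    ylim = c(0, 1), ...)
  graphics::abline(h = x$target, lty = 2)
  graphics::legend("bottomright", legend = names(x$results),
                   col = seq_len(ncol(mat)), lty = 1, pch = 19, cex = 0.8)
  invisible(x)
}
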