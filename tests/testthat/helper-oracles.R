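# Independent oracles: definitional, enumeration-based implementations used
# only to check the package's algorithms.

# Brute-force bout oracle: enumerate every (start, end) window that satisfies
# the bout definition -- ends on MVPA epochs, minimum span, minimum MVPA
# fraction, no over-long interior run of non-MVPA, no unlabelled epoch --
# then apply maximal non-overlapping selection (earliest start, longest end,
# resume after).
oracle_bouts <- function(labels, epoch_len = 5, min_bout = 10,
                         min_fraction = 0.8) {
  n <- length(labels)
  is_m <- !is.na(labels) & labels == "mvpa"
  is_na <- is.na(labels)
  min_ep <- ceiling(min_bout * 60 / epoch_len - 1e-9)
  max_gap <- floor((1 - min_fraction) * min_bout * 60 / epoch_len + 1e-9)
  starts <- ends <- integer(0)
  for (s in which(is_m)) {
    nm <- 0L; gap <- 0L; maxgap <- 0L
    for (e in s:n) {
      if (is_na[e]) break
      if (is_m[e]) { nm <- nm + 1L; gap <- 0L }
      else { gap <- gap + 1L; if (gap > maxgap) maxgap <- gap }
      len <- e - s + 1L
      if (is_m[e] && len >= min_ep && nm / len >= min_fraction &&
          maxgap <= max_gap) {
        starts <- c(starts, s); ends <- c(ends, e)
      }
    }
  }
  sel_s <- sel_e <- integer(0)
  last <- 0L
  repeat {
    cand <- starts > last
    if (!any(cand)) break
    s0 <- min(starts[cand])
    e0 <- max(ends[cand & starts == s0])
    sel_s <- c(sel_s, s0); sel_e <- c(sel_e, e0)
    last <- e0
  }
  data.frame(start_epoch = sel_s, end_epoch = sel_e)
}

# One-way ANOVA ICC via R's own linear-model machinery (independent of the
# package's definitional sums of squares).
oracle_icc <- function(v) {
  df <- data.frame(y = as.vector(v),
                   subj = factor(rep(seq_len(nrow(v)), times = ncol(v))))
  a <- anova(lm(y ~ subj, data = df))
  msb <- a$`Mean Sq`[1]
  msw <- a$`Mean Sq`[2]
  k <- ncol(v)
  (msb - msw) / (msb + (k - 1) * msw)
}

# Kruskal-Wallis H from the definitional rank computation (with tie
# correction).
oracle_kw_stat <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Random label sequence generator for bout property tests.
random_labels <- function(n, p_mvpa = 0.5, p_na = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_rest <- (1 - p_mvpa - p_na) / 2
  sample(c("mvpa", "sedentary", "light", NA),
         n, replace = TRUE, prob = c(p_mvpa, p_rest, p_rest, p_na))
}

# Epoch series spanning whole calendar days with prescribed ENMO values.
make_epoch_series <- function(enmo, epoch_len = 5, nonwear = NULL,
                              start = "2012-03-05 00:00:00", id = "T") {
  epoch_series(id, epoch_len, as.POSIXct(start, tz = "UTC"), enmo,
               nonwear = nonwear)
}
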