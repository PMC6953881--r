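# Reliability: one-way ICC, Spearman-Brown prophecy, minimum-days inversion.

test_that("icc_single_day matches definitional expectations on crafted matrices", {
  # identical days per subject, differing subjects: MSW = 0, ICC = 1
  v <- matrix(rep(c(1, 5, 9), 4), nrow = 3)
  r <- icc_single_day(v)
  expect_equal(r$icc1, 1)
  expect_equal(r$msw, 0)

  # i.i.d. noise: ICC near 0 at large n
  set.seed(10)
  noise <- matrix(rnorm(3000 * 4), 3000)
  expect_equal(icc_single_day(noise)$icc1, 0, tolerance = 0.03)

  # degenerate inputs
  expect_error(icc_single_day(matrix(1, 4, 3)), class = "actdays_input_error")
  expect_error(icc_single_day(matrix(c(1, 2, NA, 4), 2)),
               class = "actdays_input_error")
  expect_error(icc_single_day(matrix(1:4, 1)), class = "actdays_input_error")

  # negative estimates are reported and flagged, not clamped
  neg <- matrix(c(1, 10, 10, 1, 1, 10), 2)  # within-variance dwarfs between
  rn <- icc_single_day(neg)
  expect_true(rn$negative)
  expect_lt(rn$icc1, 0)
})

test_that("icc_single_day equals the ANOVA oracle on random matrices", {
  set.seed(77)
  for (i in 1:100) {
    v <- matrix(rnorm(15, sd = runif(1, 0.5, 3)) + rep(rnorm(5, sd = 2), 3),
                nrow = 5, ncol = 3)
    expect_equal(icc_single_day(v)$icc1, oracle_icc(v), tolerance = 1e-10)
  }
})

test_that("spearman_brown reproduces its closed form and boundary behaviour", {
  expect_equal(spearman_brown(0.44, 6), 6 * 0.44 / (1 + 5 * 0.44))
  expect_equal(spearman_brown(0.5, 1), 0.5)     # identity at k = 1
  expect_equal(spearman_brown(1, 4), 1)          # fixed point at 1
  expect_error(spearman_brown(0, 5), class = "actdays_domain_error")
  expect_error(spearman_brown(-0.2, 5), class = "actdays_domain_error")
  expect_error(spearman_brown(1.1, 5), class = "actdays_domain_error")
  expect_error(spearman_brown(0.5, 2.5), class = "actdays_domain_error")
})

test_that("spearman_brown is strictly increasing in r1 and k on (0,1)", {
  rs <- seq(0.05, 0.95, by = 0.05)
  for (k in c(1, 2, 3, 6, 10)) {
    vals <- vapply(rs, spearman_brown, numeric(1), k = k)
    expect_true(all(diff(vals) > 0))
  }
  for (r in c(0.1, 0.44, 0.54, 0.9)) {
    expect_true(all(diff(spearman_brown(r, 1:10)) > 0))
  }
})

test_that("min_days inverts the prophecy with correct boundary semantics", {
  expect_identical(min_days(0.44, 0.70), 3L)
  expect_identical(min_days(0.54, 0.70), 2L)
  expect_identical(min_days(0.70, 0.70, strict = TRUE), 2L)
  expect_identical(min_days(0.70, 0.70, strict = FALSE), 1L)
  expect_identical(min_days(0.9, 0.70), 1L)
  expect_error(min_days(0, 0.7), class = "actdays_domain_error")
  expect_error(min_days(0.5, 1.2), class = "actdays_config_error")

  # inverse consistency: just below the k-day reliability, k days are needed
  for (r in c(0.2, 0.44, 0.54, 0.8)) {
    for (k in 2:8) {
      expect_identical(min_days(r, spearman_brown(r, k) - 1e-9), as.integer(k))
    }
  }
  # exhaustive agreement with naive search
  naive <- function(r, t) { k <- 1L; while (spearman_brown(r, k) <= t) k <- k + 1L; k }
  for (r in seq(0.05, 0.95, by = 0.1)) {
    for (t in c(0.5, 0.7, 0.8, 0.9)) {
      expect_identical(min_days(r, t), naive(r, t))
    }
  }
})

test_that("estimated min_days matches the closed-form truth in most seeds at n = 500", {
  # sigma_b = 9, sigma_w = 7 puts the true ICC (0.623) in the middle of the
  # min_days = 2 region (0.5385, 0.70], about 4 sampling SDs from either
  # inversion boundary, so the discrete estimate should essentially always
  # agree with the closed form at this sample size
  truth <- 81 / 130
  truth_md <- min_days(truth, 0.70)
  hits <- 0L
  for (s in 1:20) {
    m <- simulate_construct_matrix(cohort_sim_config(
      n_subjects = 500, n_days = 6, sigma_between = 9, sigma_within = 7,
      seed = 500 + s))
    est <- icc_single_day(m)$icc1
    hits <- hits + (min_days(est, 0.70) == truth_md)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("reliability_report assembles curves, minimum days and flags", {
  m <- simulate_construct_matrix(cohort_sim_config(
    n_subjects = 200, n_days = 6, sigma_between = 1, sigma_within = 1, seed = 3))
  mats <- list(g1 = list(overall = m, lpa = m, mvpa = m))
  rep6 <- reliability_report(mats, K = 6, target = 0.70)
  expect_length(rep6$results, 3)
  expect_equal(nrow(rep6$curves), 18)
  for (r in rep6$results) {
    expect_equal(unname(r$r_by_days[1]), r$icc1)           # k = 1 is the ICC
    expect_true(all(diff(r$r_by_days) > 0))                # strictly increasing
    expect_identical(r$min_days, min_days(r$icc1, 0.70))
  }

  # perfectly reliable construct: flat curve at 1, one day suffices
  perfect <- construct_matrix("overall", matrix(rep(c(1, 5, 9), 3), 3))
  rp <- reliability_report(list(all = list(overall = perfect)))
  expect_equal(unname(rp$results[[1]]$r_by_days), rep(1, 6))
  expect_identical(rp$results[[1]]$min_days, 1L)

  # negative ICC: flagged, prophecy skipped
  neg <- construct_matrix("overall", matrix(c(1, 10, 10, 1, 1, 10), 2))
  rn <- reliability_report(list(all = list(overall = neg)))
  expect_true(rn$results[[1]]$negative)
  expect_true(is.na(rn$results[[1]]$min_days))
  expect_true(all(is.na(rn$results[[1]]$r_by_days[-1])))
})

test_that("a synthetic cohort tuned to icc 0.44 lands on the known curve endpoints", {
  # sigma ratio chosen so sigma_b^2/(sigma_b^2+sigma_w^2) = 0.44 exactly
  sw <- sqrt(56 / 44)
  cfg <- cohort_sim_config(n_subjects = 4000, n_days = 6, sigma_between = 1,
                           sigma_within = sw, seed = 9)
  m <- simulate_construct_matrix(cfg)
  expect_equal(m$truth$icc_true, 0.44, tolerance = 1e-12)
  est <- icc_single_day(m)$icc1
  expect_lt(abs(est - 0.44), 0.02)
  rp <- reliability_report(m, K = 6)
  curve <- rp$results[[1]]$r_by_days
  expect_equal(unname(curve[1]), est)
  expect_equal(unname(curve[6]), spearman_brown(est, 6))
  expect_equal(spearman_brown(0.44, 6), 0.825, tolerance = 1e-12)
})
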