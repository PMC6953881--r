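# Constructs stage: intensity classification, bouts, day summaries,
# analytical-sample selection.

test_that("classify_epochs applies the intensity band boundaries", {
  ep <- make_epoch_series(c(100, 50, 49.9, 100.1, 0, 120),
                          nonwear = c(rep(FALSE, 5), TRUE))
  lab <- classify_epochs(ep)
  expect_identical(lab, c("light", "light", "sedentary", "mvpa", "sedentary", NA))
  expect_error(classify_epochs(ep, lpa_low = 100, mvpa_threshold = 100),
               class = "actdays_config_error")
})

test_that("bout detection handles the canonical boundary cases", {
  # 120 five-second MVPA epochs = exactly 10 min: one pure bout
  b <- detect_mvpa_bouts(rep("mvpa", 120), epoch_len = 5)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_min, 10)
  expect_equal(b$fraction_above, 1)

  # 9 min 55 s falls short
  expect_equal(nrow(detect_mvpa_bouts(c(rep("mvpa", 119), "sedentary"),
                                      epoch_len = 5)), 0)

  # an interruption longer than (1 - fraction) * min_bout breaks the bout
  lab <- c(rep("mvpa", 60), rep("sedentary", 25), rep("mvpa", 60))
  expect_equal(nrow(detect_mvpa_bouts(lab, epoch_len = 5)), 0)
  lab2 <- c(rep("mvpa", 60), rep("sedentary", 24), rep("mvpa", 60))
  b2 <- detect_mvpa_bouts(lab2, epoch_len = 5)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_epochs, 144)
  expect_gte(b2$fraction_above, 0.8)

  # non-wear breaks unconditionally, even a single epoch
  lab3 <- c(rep("mvpa", 60), NA, rep("mvpa", 60))
  expect_equal(nrow(detect_mvpa_bouts(lab3, epoch_len = 5)), 0)
})

test_that("greedy bout scan equals the brute-force window oracle", {
  params <- expand.grid(min_bout = c(1, 2), min_fraction = c(0.6, 0.8, 1))
  n_cases <- 150
  for (case in seq_len(n_cases)) {
    p <- params[1 + (case %% nrow(params)), ]
    lab <- random_labels(sample(20:300, 1), p_mvpa = runif(1, 0.2, 0.8),
                         p_na = 0.05, seed = 1000 + case)
    got <- detect_mvpa_bouts(lab, epoch_len = 5, min_bout = p$min_bout,
                             min_fraction = p$min_fraction)
    want <- oracle_bouts(lab, epoch_len = 5, min_bout = p$min_bout,
                         min_fraction = p$min_fraction)
    expect_identical(got$start_epoch, want$start_epoch,
                     info = sprintf("case %d (starts)", case))
    expect_identical(got$end_epoch, want$end_epoch,
                     info = sprintf("case %d (ends)", case))
  }
})

test_that("summarize_day computes wear, constructs and the 16-h validity flag", {
  epd <- 17280  # 5-s epochs per day
  # day 1: full wear, constant 20 mg (sedentary); day 2: 9-h non-wear gap
  enmo <- rep(20, 2 * epd)
  nonwear <- rep(FALSE, 2 * epd)
  nonwear[epd + seq_len(9 * 720)] <- TRUE
  ep <- make_epoch_series(enmo, nonwear = nonwear)  # starts Monday 2012-03-05
  days <- summarize_day(ep)
  expect_equal(nrow(days), 2)
  expect_equal(days$dow, c(1, 2))
  expect_equal(days$wear_hours, c(24, 15))
  expect_identical(days$valid, c(TRUE, FALSE))
  expect_equal(days$overall_pa_mg, c(20, 20))
  expect_equal(days$lpa_min, c(0, 0))
  expect_equal(days$mvpa_bouted_min, c(0, 0))

  # 15.9 h of wear is invalid, 16 h is valid
  nw <- rep(TRUE, epd); nw[seq_len(round(15.9 * 720))] <- FALSE
  d159 <- summarize_day(make_epoch_series(rep(20, epd), nonwear = nw))
  expect_false(d159$valid)
  nw16 <- rep(TRUE, epd); nw16[seq_len(16 * 720)] <- FALSE
  expect_true(summarize_day(make_epoch_series(rep(20, epd), nonwear = nw16))$valid)

  # a day with zero wear carries an undefined overall PA
  allnw <- summarize_day(make_epoch_series(rep(0, epd), nonwear = rep(TRUE, epd)))
  expect_true(is.na(allnw$overall_pa_mg))
  expect_false(allnw$valid)

  # partial first/last days are excluded (26 h from 23:00 covers one
  # complete calendar day)
  part <- make_epoch_series(rep(20, epd + 2 * 720),
                            start = "2012-03-05 23:00:00")
  dpart <- summarize_day(part)
  expect_equal(nrow(dpart), 1)
  expect_equal(dpart$date, as.Date("2012-03-06"))
  expect_error(summarize_day(make_epoch_series(rep(20, 100))),
               class = "actdays_input_error")
})

test_that("minute accounting closes: sedentary + LPA + unbouted MVPA = wear", {
  cfg <- epoch_sim_config(n_subjects = 3, n_days = 2, nonwear_day_prob = 0.5,
                          nonwear_hours_range = c(1, 6), seed = 33)
  for (i in 1:3) {
    ep <- simulate_epoch_series(cfg, i)
    days <- summarize_day(ep)
    expect_equal(days$sedentary_min + days$lpa_min + days$mvpa_unbouted_min,
                 days$wear_hours * 60)
    expect_true(all(days$lpa_min + days$mvpa_bouted_min <= days$wear_hours * 60))
    # bouted minutes can exceed unbouted only by included interruptions,
    # which occupy at most (1 - bout fraction) of total bouted time
    expect_lte(sum(days$mvpa_bouted_min),
               sum(days$mvpa_unbouted_min) + 0.2 * sum(days$mvpa_bouted_min) + 1e-9)
  }
})

test_that("raising the wear criterion never increases valid days", {
  cfg <- epoch_sim_config(n_subjects = 2, n_days = 4, nonwear_day_prob = 0.8,
                          nonwear_hours_range = c(4, 12), seed = 44)
  ep <- simulate_epoch_series(cfg, 1)
  labels <- classify_epochs(ep)
  bouts <- detect_mvpa_bouts(labels, epoch_len = ep$epoch_len)
  n_valid <- vapply(c(8, 12, 16, 20, 23),
                    function(h) sum(summarize_day(ep, labels, bouts,
                                                  min_wear_hours = h)$valid),
                    numeric(1))
  expect_true(all(diff(n_valid) <= 0))
})

test_that("generator state occupancy is recovered in the day constructs", {
  # multipliers pinned to 1 and mild epoch noise, so state ENMO levels stay
  # inside their intensity bands and classified minutes track occupancy
  cfg <- epoch_sim_config(n_subjects = 2, n_days = 2, nonwear_day_prob = 0,
                          subject_sd_log = 0, day_sd_log = 0,
                          epoch_sd_log = 0.05, seed = 55)
  ep <- simulate_epoch_series(cfg, 1)
  days <- summarize_day(ep)
  st <- matrix(ep$truth$state_minutes, nrow = 1440)  # minutes x days
  expect_true(all(abs(days$lpa_min - colSums(st == 3)) <= 2))
  expect_true(all(abs(days$mvpa_unbouted_min - colSums(st == 4)) <= 2))
})

test_that("analytical-sample selection keeps first k valid days of qualifying subjects", {
  mk_days <- function(id, valid) data.frame(
    subject_id = id, date = as.Date("2012-03-05") + seq_along(valid) - 1,
    dow = iso_dow_vec(seq_along(valid)),
    wear_hours = ifelse(valid, 20, 10),
    overall_pa_mg = seq_along(valid) + 100,
    lpa_min = seq_along(valid), mvpa_bouted_min = rev(seq_along(valid)),
    mvpa_unbouted_min = 0, sedentary_min = 0, valid = valid)
  iso_dow_vec <- function(i) ((i - 1) %% 7) + 1  # Monday start
  days <- rbind(mk_days("A", rep(TRUE, 7)),
                mk_days("B", c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)),
                mk_days("C", rep(c(TRUE, FALSE), length.out = 7)))
  sel <- select_analytical_sample(days, min_valid_days = 6, k_keep = 6)
  expect_equal(sel$n_included, 1)
  expect_equal(sel$n_excluded, 2)
  expect_identical(sel$included_ids, "A")
  # chronological rule: first six of A's seven days
  expect_equal(unname(sel$matrices$overall$values[1, ]), 101:106)

  sel2 <- select_analytical_sample(days, min_valid_days = 5, k_keep = 5)
  expect_equal(sel2$n_included, 2)
  expect_equal(unname(sel2$matrices$overall$values["B", ]),
               c(1, 2, 4, 5, 7) + 100)

  expect_error(select_analytical_sample(days, min_valid_days = 8, k_keep = 6),
               class = "actdays_input_error")
  expect_error(select_analytical_sample(days, min_valid_days = 6, k_keep = 7),
               class = "actdays_config_error")
})

test_that("a simulated cohort with complete wear yields a full balanced matrix", {
  cfg <- epoch_sim_config(n_subjects = 8, n_days = 6, nonwear_day_prob = 0,
                          seed = 66)
  days <- do.call(rbind, lapply(1:8, function(i)
    summarize_day(simulate_epoch_series(cfg, i))))
  sel <- select_analytical_sample(days)
  expect_equal(dim(sel$matrices$overall$values), c(8, 6))
  expect_equal(sel$n_excluded, 0)
})
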