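# Signal stage: calibration, abnormal screening, ENMO, non-wear.

test_that("autocalibrate recovers injected offsets and gains from still data", {
  rec <- simulate_still_recording(axis_offsets = c(0.1, -0.05, 0.02),
                                  axis_gains = c(1.02, 0.98, 1.01), seed = 3)
  cal <- autocalibrate(rec)
  expect_true(cal$converged)
  expect_equal(cal$offset, c(0.1, -0.05, 0.02), tolerance = 0.01)
  expect_equal(cal$gain, c(1.02, 0.98, 1.01), tolerance = 0.01)
  expect_lt(cal$post_error, cal$pre_error)
  expect_lt(cal$post_error, 2)  # residual error under 2 mg

  # idempotence: calibrating the calibrated recording is a near-identity
  cal2 <- autocalibrate(apply_calibration(rec, cal))
  expect_equal(cal2$offset, c(0, 0, 0), tolerance = 0.005)
  expect_equal(cal2$gain, c(1, 1, 1), tolerance = 0.005)
})

test_that("autocalibrate is honest about degenerate inputs", {
  # perfectly calibrated: near-identity model, tiny error
  rec <- simulate_still_recording(seed = 9)
  cal <- autocalibrate(rec)
  expect_equal(cal$offset, c(0, 0, 0), tolerance = 0.005)
  expect_equal(cal$gain, c(1, 1, 1), tolerance = 0.005)

  # no still windows at all: identity fallback, converged = FALSE
  set.seed(1)
  n <- 40 * 3600
  noisy <- raw_recording("N", 10, as.POSIXct("2012-03-05", tz = "UTC"),
                         rnorm(n, 0, 0.5), rnorm(n, 0, 0.5), rnorm(n, 1, 0.5))
  calb <- autocalibrate(noisy)
  expect_false(calb$converged)
  expect_identical(calb$offset, c(0, 0, 0))
  expect_identical(calb$gain, c(1, 1, 1))

  # single orientation: offsets/gains not separable -> identity fallback
  one <- raw_recording("O", 10, as.POSIXct("2012-03-05", tz = "UTC"),
                       rep(0.1, n), rep(0.05, n), rep(1.05, n))
  expect_false(autocalibrate(one)$converged)

  # too short is an input error
  short <- raw_recording("S", 10, Sys.time(), rep(0, 100), rep(0, 100), rep(1, 100))
  expect_error(autocalibrate(short), class = "actdays_input_error")
})

test_that("screen_abnormal flags and clips out-of-range samples", {
  x <- c(0, 0, 12, 0); y <- rep(0, 4); z <- c(1, 1, 1, -9)
  rec <- screen_abnormal(raw_recording("A", 1, Sys.time(), x, y, z))
  expect_identical(rec$abnormal, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(rec$x[3], 8)
  expect_equal(rec$z[4], -8)

  clean <- screen_abnormal(raw_recording("B", 1, Sys.time(), y, y, z[1:4] * 0 + 1))
  expect_false(any(clean$abnormal))

  sp <- simulate_raw_recording(signal_sim_config(sample_rate = 5, days = 0.25,
                                                 spike_rate = 30, seed = 6))
  scr <- screen_abnormal(sp)
  expect_equal(sum(scr$abnormal), length(sp$truth$spike_index))
})

test_that("compute_enmo matches hand-computed epoch values", {
  t0 <- as.POSIXct("2012-03-05", tz = "UTC")  # 2 Hz: 10 samples per 5-s epoch
  still <- raw_recording("A", 2, t0, rep(0, 20), rep(0, 20), rep(1, 20))
  expect_equal(compute_enmo(still, epoch_len = 5)$enmo, rep(0, 2))

  lifted <- raw_recording("A", 2, t0, rep(0, 20), rep(0, 20), rep(1.15, 20))
  expect_equal(compute_enmo(lifted, epoch_len = 5)$enmo, rep(150, 2))

  # alternating magnitudes 1.2 / 0.9: truncation gives (200 + 0)/2 = 100 mg,
  # the absolute-value reading gives (200 + 100)/2 = 150 mg
  mags <- rep(c(1.2, 0.9), 5)
  alt <- raw_recording("A", 2, t0, rep(0, 10), rep(0, 10), mags)
  expect_equal(compute_enmo(alt, epoch_len = 5)$enmo, 100)
  expect_equal(compute_enmo(alt, epoch_len = 5, negatives = "absolute")$enmo,
               150)

  # trailing partial epoch dropped
  odd <- raw_recording("A", 2, t0, rep(0, 23), rep(0, 23), rep(1, 23))
  expect_length(compute_enmo(odd, epoch_len = 5)$enmo, 2)

  empty <- raw_recording("A", 2, t0, numeric(0), numeric(0), numeric(0))
  expect_error(compute_enmo(empty), class = "actdays_input_error")
  expect_error(compute_enmo(still, epoch_len = 0.1),
               class = "actdays_input_error")
})

test_that("ENMO is invariant to rigid rotation of a constant-magnitude signal", {
  set.seed(4)
  th <- runif(1, 0, 2 * pi); ph <- runif(1, 0, pi)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  v <- matrix(rnorm(3 * 100), 3)
  v <- 1.08 * sweep(v, 2, sqrt(colSums(v^2)), "/")  # constant magnitude 1.08
  t0 <- as.POSIXct("2012-03-05", tz = "UTC")
  a <- raw_recording("A", 2, t0, v[1, ], v[2, ], v[3, ])
  vr <- R %*% v
  b <- raw_recording("B", 2, t0, vr[1, ], vr[2, ], vr[3, ])
  expect_equal(compute_enmo(a, epoch_len = 5)$enmo,
               compute_enmo(b, epoch_len = 5)$enmo, tolerance = 1e-9)
})

test_that("compute_enmo recovers generator ground truth within noise tolerance", {
  cfg <- signal_sim_config(sample_rate = 20, days = 0.5, seed = 12)
  rec <- simulate_raw_recording(cfg)
  ep <- compute_enmo(rec, epoch_len = 5)
  expect_lt(mean(abs(ep$enmo - rec$truth$enmo)), 5)
})

test_that("abnormal mask propagates to epochs under the majority rule", {
  t0 <- as.POSIXct("2012-03-05", tz = "UTC")
  z <- rep(1, 20)
  z[1:3] <- 20          # 3 of 5 samples in epoch 1 out of range
  z[6] <- 20            # 1 of 5 in epoch 2
  rec <- screen_abnormal(raw_recording("A", 1, t0, rep(0, 20), rep(0, 20), z))
  ep <- compute_enmo(rec, epoch_len = 5)
  expect_identical(ep$abnormal, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(ep$wear, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("detect_nonwear separates still gaps from active wear", {
  # active 24-h signal, no gaps: 100% wear
  active <- simulate_raw_recording(signal_sim_config(sample_rate = 5, days = 1,
                                                     seed = 13))
  expect_equal(sum(detect_nonwear(active, epoch_len = 5)), 0)

  # injected 9-h gap recovered within 30 min
  gap <- simulate_raw_recording(signal_sim_config(
    sample_rate = 5, days = 1, nonwear_windows = list(c(12, 9)), seed = 14))
  nw <- detect_nonwear(gap, epoch_len = 5)
  expect_equal(sum(nw) * 5 / 3600, 9, tolerance = 0.5)

  # fully still day: zero wear epochs
  t0 <- as.POSIXct("2012-03-05", tz = "UTC")
  n <- 86400 * 2
  set.seed(2)
  still <- raw_recording("S", 2, t0, rnorm(n, 0, 0.002), rnorm(n, 0, 0.002),
                         rnorm(n, 1, 0.002))
  ep <- flag_nonwear(compute_enmo(still, epoch_len = 5),
                     detect_nonwear(still, epoch_len = 5))
  expect_equal(sum(ep$wear), 0)

  # shorter than one window: full wear plus a warning
  shrt <- raw_recording("S", 2, t0, rnorm(600), rnorm(600), rnorm(600, 1))
  expect_warning(nw2 <- detect_nonwear(shrt, epoch_len = 5), "full wear")
  expect_false(any(nw2))
})
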