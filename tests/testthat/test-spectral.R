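test_that("estimate_isf matches an independent periodogram argmax", {
  set.seed(21)
  for (rep in 1:12) {
    f <- sample(8:13, 1)
    ts <- sine_trial_set(f, 1, n_unit = 2, n_trial = 4, fs = 250,
                         dur = 2, noise_sd = 0.3, seed = 1000 + rep)
    sp <- estimate_isf(ts, freqs = 4:40)
    # oracle: direct complex-sum periodogram, averaged over units/trials
    pow <- vapply(4:40, function(fr) {
      mean(apply(ts$data, c(2, 3), function(x)
        oracle_taper_power(x, fr, ts$sampling_rate)))
    }, 0)
    band <- (4:40) >= 7 & (4:40) <= 14
    expect_equal(sp$isf, (4:40)[band][which.max(pow[band])])
    expect_equal(sp$isf, f)
  }
})

test_that("the ISF search is restricted to the broad alpha band", {
  # strongest peak at 6 Hz, secondary at 11 Hz -> 11 wins inside 7-14
  ts <- sine_trial_set(c(6, 11), c(3, 1), fs = 250, dur = 2)
  expect_equal(estimate_isf(ts)$isf, 11)
})

test_that("exact power ties resolve to the lower frequency, with a message", {
  # impulse triplet orthogonal to the detrend basis: power at f is
  # (h_c - h_{c+k} cos(2 pi f k / fs))^2, and fs = 19 k makes the cosine
  # (hence the power) exactly equal at 9 and 10 Hz, maximal in-band
  fs <- 950; k <- 50; n <- 951; c0 <- 476
  x <- numeric(n)
  x[c0] <- 1; x[c0 - k] <- -0.5; x[c0 + k] <- -0.5
  ts <- trial_set(array(x, c(n, 1, 1)), 0, fs, "baseline")
  expect_message(sp <- estimate_isf(ts), "tie")
  expect_equal(sp$isf, 9)
  p <- sp$power
  expect_equal(p[sp$freqs == 9], p[sp$freqs == 10])
  expect_true(all(p[sp$freqs %in% c(7, 8, 11, 12, 13, 14)] <
                  p[sp$freqs == 9]))
})

test_that("an empty alpha band raises a descriptive error", {
  ts <- sine_trial_set(20, 1, fs = 250, dur = 2)  # power only at 20 Hz
  expect_error(estimate_isf(ts, freqs = c(9, 10, 11, 20)), NA)
  zero <- trial_set(array(0, c(500, 1, 2)), 0, 250, "baseline")
  expect_error(estimate_isf(zero), "no alpha peak")
})

test_that("single-window and per-trial ISF estimates agree on clean data", {
  ts <- sine_trial_set(11, 1, n_trial = 6, fs = 250, dur = 2,
                       noise_sd = 0.2, seed = 5)
  expect_equal(estimate_isf(ts, window = "per_trial")$isf, 11)
  expect_equal(estimate_isf(ts, window = "single")$isf, 11)
})

test_that("TFR power scales quadratically and peaks at the tone frequency", {
  ts1 <- sine_trial_set(10, 1, fs = 250, dur = 3, n_trial = 2)
  ts2 <- sine_trial_set(10, 2, fs = 250, dur = 3, n_trial = 2)
  tf1 <- compute_tfr(ts1, "cycles7")
  tf2 <- compute_tfr(ts2, "cycles7")
  mid <- which.min(abs(tf1$times - 1.5))
  spec_mid <- tf1$power[, mid, 1, 1]
  expect_equal(tf1$freqs[which.max(spec_mid)], 10)
  # amplitude 2A vs A: power ratio exactly 4
  expect_equal(tf2$power[tf2$freqs == 10, mid, 1, 1] /
                 tf1$power[tf1$freqs == 10, mid, 1, 1], 4,
               tolerance = 1e-10)
})

test_that("TFR time grid, edge handling and window lengths follow the contract", {
  ts <- sine_trial_set(10, 1, fs = 250, dur = 3, n_trial = 1)
  tf <- compute_tfr(ts, "cycles7")
  expect_equal(unique(round(diff(tf$times), 10)), 0.1)
  # 7 cycles at 10 Hz = 0.7 s window: first valid centre >= 0.35 s
  p10 <- tf$power[tf$freqs == 10, , 1, 1]
  first_valid <- tf$times[which(!is.na(p10))[1]]
  expect_gte(first_valid, 0.35)
  expect_lt(first_valid, 0.45)
  # incomplete windows are NA, not zero
  expect_true(all(is.na(p10[tf$times < 0.35])))
  # 5 Hz needs 1.4 s: a 1 s epoch errors naming the frequency
  short <- sine_trial_set(10, 1, fs = 250, dur = 1)
  expect_error(compute_tfr(short, "cycles7"), "5 Hz")
  # fixed 400 ms variant tolerates the short epoch
  expect_s3_class(compute_tfr(short, "win400ms", freqs = 8:12), "tfr")
})

test_that("TFR of a stationary tone is invariant to whole-step time shifts", {
  fs <- 250; n <- 750
  lag <- 50  # two 100 ms steps
  tfull <- (0:(n + lag - 1)) / fs
  xfull <- sin(2 * pi * 10 * tfull)
  x1 <- xfull[1:n]
  x2 <- xfull[(lag + 1):(n + lag)]  # exact whole-step sample shift
  tfa <- compute_tfr(trial_set(array(x1, c(n, 1, 1)), 0, fs, "post"),
                     "cycles7", freqs = 10)
  tfb <- compute_tfr(trial_set(array(x2, c(n, 1, 1)), 0, fs, "post"),
                     "cycles7", freqs = 10)
  va <- tfa$power[1, , 1, 1]; vb <- tfb$power[1, , 1, 1]
  # window at centre t of the shifted tone is the window at t + 0.2 of
  # the original
  j <- which(!is.na(vb) & !is.na(va[seq_along(vb) + 2]))
  expect_gt(length(j), 10)
  expect_equal(vb[j], va[j + 2], tolerance = 1e-8)
})

test_that("fundamental alignment maps offsets to ISF-relative frequencies", {
  ts <- sine_trial_set(10, 1, fs = 250, dur = 3, n_trial = 2)
  tf <- compute_tfr(ts, "cycles7")
  al <- align_tfr(tf, isf = 10)
  expect_equal(al$offsets, -2:26)
  expect_length(al$offsets, 29)
  expect_equal(al$abs_freqs[1], 8)
  expect_equal(al$abs_freqs[29], 36)
  # offset k row holds the power at isf + k
  expect_equal(al$power[al$offsets == 0, , 1, 1],
               tf$power[tf$freqs == 10, , 1, 1])
  expect_equal(al$power[al$offsets == -2, , 1, 1],
               tf$power[tf$freqs == 8, , 1, 1])
  # round trip: non-missing bins restore absolute frequencies
  expect_true(all(al$abs_freqs == al$isf_used + al$offsets))
  expect_false(anyNA(al$power[, 15, 1, 1]))
})

test_that("harmonic alignment centres on 2*ISF and marks out-of-range bins missing", {
  ts <- sine_trial_set(20, 1, fs = 250, dur = 3, n_trial = 1)
  tf <- compute_tfr(ts, "cycles7")
  al <- align_tfr(tf, isf = 10, mode = "harmonic")
  expect_equal(al$offsets, -4:16)
  expect_equal(al$abs_freqs[al$offsets == 0], 20)
  expect_equal(al$power[al$offsets == 0, , 1, 1],
               tf$power[tf$freqs == 20, , 1, 1])
  # isf = 13: 2*13 + 16 = 42 Hz exceeds the 40 Hz ceiling -> missing
  al13 <- align_tfr(tf, isf = 13, mode = "harmonic")
  expect_true(all(is.na(al13$power[al13$abs_freqs > 40, , , ])))
  expect_false(anyNA(al13$power[al13$abs_freqs <= 40, 15, , ]))
})
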