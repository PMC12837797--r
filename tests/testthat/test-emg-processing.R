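test_that("rest baseline captures DC offset and rest envelope level", {
  const <- emg_trace(rep(3.2, 500), 2000, "RES", "rest")
  bl <- compute_rest_baseline(const)
  expect_equal(bl$dc_offset, 3.2)
  expect_equal(bl$rest_envelope_level, 0)

  alt <- emg_trace(rep(c(1, -1), 250), 2000, "RES", "rest")
  expect_equal(compute_rest_baseline(alt)$dc_offset, 0)

  set.seed(42)
  x <- rnorm(10000, mean = 5, sd = 1)
  bl <- compute_rest_baseline(emg_trace(x, 2000, "LES", "rest"))
  expect_lt(abs(bl$dc_offset - 5), 3 / sqrt(10000))
  expect_error(compute_rest_baseline(emg_trace(numeric(0), 2000, "RES")),
               "empty")
})

test_that("DC offset removal subtracts the scalar rest mean", {
  tr <- emg_trace(c(2, 4, 6), 100, "RRA", "vct")
  bl0 <- structure(list(channel = "RRA", dc_offset = 0,
                        rest_envelope_level = 0), class = "rest_baseline")
  expect_equal(remove_dc_offset(tr, bl0)$samples, tr$samples)
  blc <- structure(list(channel = "RRA", dc_offset = 4,
                        rest_envelope_level = 0), class = "rest_baseline")
  expect_equal(mean(remove_dc_offset(tr, blc)$samples), 0)
  expect_equal(remove_dc_offset(emg_trace(rep(4, 5), 100, "RRA"), blc)$samples,
               rep(0, 5))
  wrong <- structure(list(channel = "LRA", dc_offset = 4,
                          rest_envelope_level = 0), class = "rest_baseline")
  expect_error(remove_dc_offset(tr, wrong), "channel mismatch")
})

test_that("offset removal is idempotent when the baseline is recomputed", {
  set.seed(7)
  rest <- emg_trace(2 + rnorm(4000), 2000, "REO", "rest")
  once <- remove_dc_offset(rest, compute_rest_baseline(rest))
  twice <- remove_dc_offset(once, compute_rest_baseline(once))
  expect_equal(twice$samples, once$samples, tolerance = 1e-12)
})

test_that("RMS envelope: constants, degenerate window, hand arithmetic", {
  const <- emg_trace(rep(-1.5, 100), 1000, "RES", "vct")
  expect_equal(rms_envelope(const)$samples, rep(1.5, 100))

  x <- emg_trace(c(-3, 2, -1, 4), 1000, "RES", "vct")
  expect_equal(rms_envelope(x, 1)$samples, abs(x$samples))

  y <- rms_envelope(emg_trace(c(3, 4, 0), 1000, "RES", "vct"), 3)
  expect_equal(y$samples[2], sqrt((9 + 16 + 0) / 3))
  # edges truncate the window instead of padding
  expect_equal(y$samples[1], sqrt((9 + 16) / 2))
  expect_length(y$samples, 3)
  expect_error(rms_envelope(x, 4), "odd")
})

test_that("RMS of a sinusoid with window >> period approaches A/sqrt(2)", {
  rate <- 1000
  t <- seq(0, 2, by = 1 / rate)
  A <- 2
  tr <- emg_trace(A * sin(2 * pi * 50 * t), rate, "LES", "vct")
  env <- rms_envelope(tr, 501)
  mid <- env$samples[500:1500]
  expect_true(all(abs(mid - A / sqrt(2)) / (A / sqrt(2)) < 0.01))
  expect_true(all(env$samples >= 0))
})

test_that("rest threshold masks sub-rest samples without altering values", {
  env <- emg_envelope(c(0.1, 0.5, 0.2), 100, "RES")
  bl <- structure(list(channel = "RES", dc_offset = 0,
                       rest_envelope_level = 0.25), class = "rest_baseline")
  out <- apply_rest_threshold(env, bl)
  expect_equal(out$zero_force_mask, c(TRUE, FALSE, TRUE))
  expect_equal(out$samples, env$samples)

  bl0 <- structure(list(channel = "RES", dc_offset = 0,
                        rest_envelope_level = 0), class = "rest_baseline")
  expect_false(any(apply_rest_threshold(env, bl0)$zero_force_mask))

  high <- structure(list(channel = "RES", dc_offset = 0,
                         rest_envelope_level = 10), class = "rest_baseline")
  expect_true(all(apply_rest_threshold(env, high)$zero_force_mask))
})

test_that("resampling is linear interpolation preserving constants and ramps", {
  const <- emg_envelope(rep(0.7, 100), 100, "RRA")
  expect_true(all(resample_to(const, 37)$samples == 0.7))
  same <- resample_to(const, 100)
  expect_equal(same$samples, const$samples)

  ramp <- emg_envelope(seq(0, 1, length.out = 101), 100, "RRA")
  out <- resample_to(ramp, 250)
  t_new <- (seq_along(out$samples) - 1) / 250
  expect_equal(out$samples, t_new, tolerance = 1e-12)
  expect_error(resample_to(ramp, -5), "target_rate")
})
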