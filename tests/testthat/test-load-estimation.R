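test_that("muscle force prediction applies rest threshold and clamping", {
  s <- seq(0.1, 1, length.out = 20)
  rel <- fit_force_emg(10 * s, s, "linear", muscle = "RES")
  bl <- structure(list(channel = "RES", dc_offset = 0,
                       rest_envelope_level = 0.5), class = "rest_baseline")
  env <- emg_envelope(c(0.2, 0.4, 2.5), 100, "RES")
  f <- predict_muscle_force(rel, env, bl)
  expect_equal(f, c(0, 0, 25), tolerance = 1e-9)
  # entirely sub-rest envelope gives an all-zero force series
  low <- emg_envelope(rep(0.1, 50), 100, "RES")
  expect_equal(predict_muscle_force(rel, low, bl), rep(0, 50))
})

test_that("torso angle from markers measures inclination from vertical", {
  sacrum <- c(0, 0, 1)
  expect_equal(torso_angle_from_markers(sacrum, sacrum + c(0, 0, 1)), 0)
  expect_equal(torso_angle_from_markers(sacrum, sacrum + c(1, 0, 0)), 90)
  expect_equal(torso_angle_from_markers(sacrum, sacrum + c(1, 0, 1)), 45)
  frames <- rbind(c(0, 0, 1), c(1, 0, 0))
  sac <- rbind(sacrum, sacrum)
  expect_equal(torso_angle_from_markers(sac, sac + frames), c(0, 90))
  expect_error(torso_angle_from_markers(sacrum, sacrum), "zero-length")
})

test_that("vertical force balance composes weight and muscle terms", {
  subj <- subject_record(mass = 700 / 9.81, height = 1.78, torso_depth = 0.2,
                         torso_width = 0.3, leg_length = 0.9)
  geom <- muscle_angles(estimate_muscle_geometry(subj), subj$lever_arm_length)
  n <- 5
  zero <- stats::setNames(rep(list(rep(0, n)), 6), EMG_CHANNELS)
  t <- seq_len(n)
  # upright with silent muscles: 67% BW
  up <- compute_load_series(zero, geom, subj, rep(0, n), t)
  expect_equal(up$f_j, rep(0.67 * 700, n))
  # horizontal torso with silent muscles: zero compression
  flat <- compute_load_series(zero, geom, subj, rep(90, n), t)
  expect_equal(flat$f_j, rep(0, n))
  # a single muscle at 90 degrees adds its full force
  g90 <- geom
  g90$inclination[g90$muscle == "ES"] <- 90
  one <- zero
  one$RES <- rep(1000, n)
  mixed <- compute_load_series(one, g90, subj, rep(0, n), t)
  expect_equal(mixed$f_j, rep(0.67 * 700 + 1000, n))
  # monotonicity: increasing any muscle force weakly increases the load
  bumped <- one
  bumped$LRA <- rep(50, n)
  expect_true(all(compute_load_series(bumped, geom, subj, rep(30, n), t)$f_j >=
                    compute_load_series(one, geom, subj, rep(30, n), t)$f_j))
  expect_error(compute_load_series(one, geom, subj, rep(0, 3), t),
               "misaligned")
})

test_that("lift-cycle segmentation counts excursions with hysteresis", {
  expect_equal(nrow(segment_lift_cycles(rep(0.1, 100))), 0)
  lift <- c(rep(0.1, 20), seq(0.1, 1, length.out = 30),
            seq(1, 0.1, length.out = 30), rep(0.1, 20))
  one <- segment_lift_cycles(lift)
  expect_equal(nrow(one), 1)
  # concatenating two identical bouts doubles the cycle count
  two <- segment_lift_cycles(c(lift, lift))
  expect_equal(nrow(two), 2)
  # an incomplete trailing lift is discarded
  trailing <- c(lift, seq(0.1, 1, length.out = 30))
  expect_equal(nrow(segment_lift_cycles(trailing)), 1)
})

test_that("segmentation recovers the constructed lift boundaries", {
  cfg <- fast_config(seed = 12, kinematic_sampling_rate = 100)
  sy <- generate_subject(cfg, 1)
  tr <- generate_slss_trial(sy, cfg)
  cyc <- segment_lift_cycles(tr$ball_height, tr$time)
  expect_equal(nrow(cyc), tr$truth$n_lifts)
  # each detected cycle lies within the constructed carrying window
  carry_t <- range(tr$time[tr$truth$carrying])
  expect_true(all(cyc$start_time >= 0 & cyc$end_time <= max(tr$time)))
})

test_that("impulse integration matches closed forms", {
  t <- seq(0, 10, by = 0.01)
  const <- data.frame(time = t, f_j = rep(500, length(t)))
  cyc <- list(start = 1, end = length(t))
  imp <- compute_impulse(const, cyc, body_weight = 700)
  expect_equal(imp$impulse, 500 * 10)
  expect_equal(imp$impulse_bw, 5000 / 700)
  # triangular load integrates to L*T/2 within one-sample discretization
  tri <- data.frame(time = t,
                    f_j = 1000 * (1 - abs(t - 5) / 5))
  imp_tri <- compute_impulse(tri, cyc, 700)
  expect_equal(imp_tri$impulse, 1000 * 10 / 2, tolerance = 0.01 / 10)
  # halving body weight doubles the normalized impulse only
  imp_half <- compute_impulse(const, cyc, body_weight = 350)
  expect_equal(imp_half$impulse, imp$impulse)
  expect_equal(imp_half$impulse_bw, 2 * imp$impulse_bw)
  # additivity over adjacent subintervals
  mid <- 500
  a <- compute_impulse(tri, list(start = 1, end = mid), 700)$impulse
  b <- compute_impulse(tri, list(start = mid, end = length(t)), 700)$impulse
  expect_equal(a + b, imp_tri$impulse)
  expect_error(compute_impulse(const, list(start = 5, end = 5), 700),
               "start < end")
})

test_that("percent-of-task normalization is sampling-rate invariant", {
  f <- function(u) 67 + 100 * sin(pi * u)^2
  coarse <- normalize_cycle_curve(f(seq(0, 1, length.out = 51)))
  fine <- normalize_cycle_curve(f(seq(0, 1, length.out = 2001)))
  expect_equal(coarse, fine, tolerance = 1e-2)
  expect_length(coarse, 101)
  const <- normalize_cycle_curve(rep(67, 10))
  expect_true(all(const == 67))
})
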