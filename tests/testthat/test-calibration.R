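test_that("gravity calibration interpolates rest torque over angle", {
  # flat zero curve: corrected moment equals raw moment (scaled by d_L)
  zero <- fit_gravity_calibration(c(0, 90), c(0, 0))
  raw <- c(10, -5, 3)
  expect_equal(correct_moment(raw, c(10, 50, 80), zero, 1), raw)
  # queries at measured angles return the measured torque exactly
  curve <- fit_gravity_calibration(seq(0, 90, by = 5),
                                   sin(seq(0, 90, by = 5) / 30))
  expect_equal(predict(curve, c(0, 45, 90)), sin(c(0, 45, 90) / 30))
  # repeated angles collapse (artifact is a function of angle only)
  dup <- fit_gravity_calibration(c(0, 45, 45, 90), c(0, 2, 2, 1))
  expect_equal(predict(dup, 45), 2)
  expect_error(fit_gravity_calibration(c(30, 30), c(1, 1)), "distinct")
  # extrapolation clamps to endpoint values
  expect_equal(predict(dup, c(-10, 200)), c(0, 1))
})

test_that("piecewise-linear calibration tracks a smooth cubic between nodes", {
  cubic <- function(a) 80 * (1.05 * (a / 90) + 0.35 * (a / 90)^2 -
                               0.55 * (a / 90)^3)
  grid <- seq(0, 90, by = 5)
  curve <- fit_gravity_calibration(grid, cubic(grid))
  q <- seq(2.5, 87.5, by = 5)
  # interpolation error bound for a cubic on a 5-degree grid: h^2/8 * max|f''|
  h <- 5 * pi / 180
  expect_lt(max(abs(predict(curve, q) - cubic(q))), 0.2)
})

test_that("extension moment balance solves and clamps the ES force", {
  expect_equal(solve_extension_force(0, 0.5, 0.05, 0)$total, 0)
  sol <- solve_extension_force(10, 0.5, 0.05, 0)
  expect_equal(sol$total, 100)
  expect_equal(sol$per_side, 50)
  # cos(60 deg) halves the denominator relative to 0 deg -> doubles force
  expect_equal(solve_extension_force(10, 0.5, 0.05, 60)$total, 200)
  expect_equal(solve_extension_force(-4, 0.5, 0.05, 0)$total, 0)
  expect_error(solve_extension_force(1, 0.5, 0.05, 90), "degenerate")
})

test_that("flexion moment balance applies the CSA-ratio split", {
  expect_equal(solve_flexion_forces(0, 1, 0.1, 0, 0.08, 1)$ra_total, 0)
  # hand calculation: M_B* d_L = 10, d_RA = 0.10, theta_RA = 0, d_EO = 0.08
  sol <- solve_flexion_forces(10, 1, 0.10, 0, 0.08, 1)
  expect_equal(sol$ra_total, 10 / (0.10 + 0.08 * cos(pi / 4)),
               tolerance = 1e-12)
  expect_equal(sol$eo_total, sol$ra_total)
  expect_equal(sol$ra_total, 63.87, tolerance = 1e-4)
  # r = 0 attributes the whole moment to the RA
  expect_equal(solve_flexion_forces(10, 1, 0.10, 0, 0.08, 0)$ra_total, 100)
  expect_equal(solve_flexion_forces(10, 1, 0.10, 0, 0.08, 0)$eo_total, 0)
})

test_that("moment balances round-trip random force/geometry draws", {
  set.seed(11)
  n <- 200
  d_l <- runif(n, 0.3, 0.7)
  d_es <- runif(n, 0.03, 0.08)
  th_es <- runif(n, 0, 40)
  f_es <- runif(n, 0, 4000)
  mb <- f_es * d_es * cospi(th_es / 180) / d_l
  back <- mapply(function(m, dl, de, te)
    solve_extension_force(m, dl, de, te)$total, mb, d_l, d_es, th_es)
  expect_lt(max(abs(back - f_es) / f_es), 1e-9)

  d_ra <- runif(n, 0.07, 0.11); th_ra <- runif(n, 0, 30)
  d_eo <- runif(n, 0.05, 0.10); r <- runif(n, 0.5, 2)
  f_ra <- runif(n, 1, 2000); f_eo <- r * f_ra
  mb <- (f_ra * d_ra * cospi(th_ra / 180) + f_eo * d_eo * cospi(0.25)) / d_l
  sol <- mapply(function(m, dl, dra, tra, deo, rr) {
    s <- solve_flexion_forces(m, dl, dra, tra, deo, rr)
    c(s$ra_total, s$eo_total)
  }, mb, d_l, d_ra, th_ra, d_eo, r)
  expect_lt(max(abs(sol[1, ] - f_ra) / f_ra), 1e-9)
  expect_lt(max(abs(sol[2, ] - f_eo) / f_eo), 1e-9)
  # printed balance residual after solving
  resid <- sol[1, ] * d_ra * cospi(th_ra / 180) +
    sol[2, ] * d_eo * cospi(0.25) - mb * d_l
  expect_lt(max(abs(resid) / (mb * d_l)), 1e-9)
})

test_that("phase labels follow the sign of the angular velocity", {
  rate <- 100
  tri <- c(seq(0, 90, length.out = 91), seq(89, 0, length.out = 90))
  ph <- label_phases(tri, rate)
  expect_true(all(ph[2:89] == "flexion"))
  expect_true(all(ph[93:179] == "extension"))
  expect_equal(ph[91], "none")  # apex sits inside the deadband
  expect_equal(label_phases(rep(5, 50), rate), rep("none", 50))
})

test_that("force-EMG pairing routes phases to muscles and honours rest masks", {
  cfg <- fast_config(seed = 3)
  sy <- generate_subject(cfg, 1)
  vct <- generate_vct(sy, cfg, 60, effort = 1)
  curve <- fit_gravity_calibration(vct$rest_sweep$angle, vct$rest_sweep$torque)
  forces <- solve_vct_forces(vct, curve, sy$truth$geometry)
  smp <- pair_force_emg(vct, forces)
  expect_true(all(smp$phase[smp$muscle %in% c("RES", "LES")] == "extension"))
  expect_true(all(smp$phase[smp$muscle %in% c("RRA", "LRA", "REO", "LEO")] ==
                    "flexion"))
  expect_true(all(smp$force >= 0) && all(smp$envelope >= 0))
  # an all-masking rest level empties the set and the fit refuses
  high <- lapply(EMG_CHANNELS, function(ch)
    structure(list(channel = ch, dc_offset = 0, rest_envelope_level = 1e6),
              class = "rest_baseline"))
  names(high) <- EMG_CHANNELS
  empty <- pair_force_emg(vct, forces, baselines = high)
  expect_equal(nrow(empty), 0)
  expect_error(fit_force_emg(empty$force, empty$envelope, "linear"),
               "at least 3")
  # mismatched timebase is an input error
  short <- vct
  short$envelopes <- vct$envelopes[1:10, ]
  expect_error(pair_force_emg(short, forces), "timebase")
})

test_that("percent error normalizes by the maximum observed force", {
  rel <- fit_force_emg(c(0, 10, 20), c(0, 1, 2), "linear")
  smp <- data.frame(force = c(10, 20), envelope = c(1.1, 1.8))
  # pred = (11, 18): mean(|1|/20, |2|/20) * 100 = 7.5
  expect_equal(percent_error(rel, smp), 7.5)
  expect_equal(percent_error(rel, data.frame(force = c(0, 10, 20),
                                             envelope = c(0, 1, 2))), 0)
  # scale invariance
  rel2 <- fit_force_emg(c(0, 20, 40), c(0, 1, 2), "linear")
  smp2 <- data.frame(force = 2 * smp$force, envelope = smp$envelope)
  expect_equal(percent_error(rel2, smp2), 7.5)
  expect_error(percent_error(rel, data.frame(force = c(0, 0),
                                             envelope = c(1, 2))), "zero")
})

test_that("form selection takes the lower percent error, ties to linear", {
  expect_equal(select_best_relationship(c(linear = 17, logarithmic = 22)),
               "linear")
  expect_equal(select_best_relationship(c(linear = 18, logarithmic = 13)),
               "logarithmic")
  expect_equal(select_best_relationship(c(linear = 15, logarithmic = 15)),
               "linear")
  expect_error(select_best_relationship(c(linear = 15)), "logarithmic")
})
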