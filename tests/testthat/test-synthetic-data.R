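test_that("generation is deterministic per (config, ids)", {
  cfg <- fast_config(seed = 5, noise_sd = 0.03)
  expect_identical(generate_subject(cfg, 2), generate_subject(cfg, 2))
  sy <- generate_subject(cfg, 2)
  expect_identical(generate_rest_trial(sy, cfg), generate_rest_trial(sy, cfg))
  expect_identical(generate_vct(sy, cfg, 60, 0.7, trial_id = 2),
                   generate_vct(sy, cfg, 60, 0.7, trial_id = 2))
  expect_identical(generate_slss_trial(sy, cfg), generate_slss_trial(sy, cfg))
  # different ids decouple
  expect_false(identical(generate_subject(cfg, 1)$subject$mass,
                         sy$subject$mass))
  expect_error(generate_subject(cfg, 99), "range")
})

test_that("cohort BMI matches the target distribution", {
  cfg <- fast_config(seed = 123, n_subjects = 1000)
  bmi <- vapply(seq_len(1000), function(i) {
    s <- generate_subject(cfg, i)$subject
    s$mass / s$height^2
  }, numeric(1))
  expect_lt(abs(mean(bmi) - 25.2), 3 * 0.8 / sqrt(1000))
  expect_true(all(bmi >= 20 & bmi <= 30))
  # degenerate range pins the BMI exactly
  cfg20 <- fast_config(seed = 1, n_subjects = 5, bmi_range = c(20, 20))
  bmi20 <- vapply(1:5, function(i) {
    s <- generate_subject(cfg20, i)$subject
    s$mass / s$height^2
  }, numeric(1))
  expect_equal(bmi20, rep(20, 5))
})

test_that("rest trials are baseline plus noise of the configured length", {
  cfg0 <- synthetic_config(seed = 1, noise_sd = 0, baseline_offset = 0.4)
  sy <- generate_subject(cfg0, 1)
  rest <- generate_rest_trial(sy, cfg0)
  expect_length(rest[["RES"]]$samples, 10000)  # 5 s at 2000 Hz
  expect_true(all(vapply(rest, function(tr)
    all(tr$samples == 0.4), logical(1))))
})

test_that("VCT geometry: triangle wave, duration, speed validation", {
  cfg <- fast_config(seed = 2)
  sy <- generate_subject(cfg, 1)
  v <- generate_vct(sy, cfg, 60, effort = 1)
  # 3 cycles x 2 x 90 deg / 60 deg/s = 9 s
  expect_equal(length(v$time) / cfg$emg_sampling_rate, 9)
  expect_equal(range(v$lever_angle), c(0, 90))
  expect_error(generate_vct(sy, cfg, 45, effort = 1), "vct_speeds")
})

test_that("zero-effort VCT records exactly the gravity-artifact curve", {
  cfg <- fast_config(seed = 4)
  sy <- generate_subject(cfg, 1)
  v0 <- generate_vct(sy, cfg, 30, effort = 0)
  curve <- fit_gravity_calibration(v0$rest_sweep$angle, v0$rest_sweep$torque)
  expect_equal(v0$torque, predict(curve, v0$lever_angle), tolerance = 1e-12)
  # gravity artifact is a function of angle only
  same_angle <- which(v0$lever_angle == v0$lever_angle[50])
  expect_true(length(same_angle) > 1)
  expect_equal(v0$torque[same_angle], rep(v0$torque[50], length(same_angle)))
})

test_that("noise-free single-sample moment balance round-trips exactly", {
  cfg <- fast_config(seed = 6)
  sy <- generate_subject(cfg, 1)
  v <- generate_vct(sy, cfg, 60, effort = 1)
  curve <- fit_gravity_calibration(v$rest_sweep$angle, v$rest_sweep$torque)
  forces <- solve_vct_forces(v, curve, sy$truth$geometry)
  ext <- forces$phase == "extension" & v$truth$f_es > 0
  expect_lt(max(abs(forces$f_es[ext] - v$truth$f_es[ext]) /
                  v$truth$f_es[ext]), 1e-9)
  fle <- forces$phase == "flexion" & v$truth$f_ra > 0
  expect_lt(max(abs(forces$f_ra[fle] - v$truth$f_ra[fle]) /
                  v$truth$f_ra[fle]), 1e-9)
  expect_lt(max(abs(forces$f_eo[fle] - v$truth$f_eo[fle]) /
                  v$truth$f_eo[fle]), 1e-9)
})

test_that("SLSS construction: lift count, holds, stored truth", {
  cfg <- fast_config(seed = 8, task_duration = 50)
  sy <- generate_subject(cfg, 1)
  tr <- generate_slss_trial(sy, cfg, n_lifts = 5)
  cyc <- segment_lift_cycles(tr$ball_height, tr$time)
  expect_equal(nrow(cyc), 5)
  # upright holds exist: at least 2 s per cycle at 0 degrees while carrying
  upright_carry <- tr$torso_angle == 0 & tr$truth$carrying
  expect_gt(sum(upright_carry) / cfg$emg_sampling_rate, 5 * 2 * 0.99)
  expect_true(all(vapply(tr$truth$forces, function(f) all(f >= 0),
                         logical(1))))
  expect_error(generate_slss_trial(sy, cfg, n_lifts = 20), "too short")
})

test_that("standing trial truth is 67% of body weight everywhere", {
  cfg <- fast_config(seed = 9)
  sy <- generate_subject(cfg, 1)
  st <- generate_standing_trial(sy, cfg)
  expect_equal(st$truth$load$f_j,
               rep(0.67 * sy$subject$body_weight, length(st$time)))
  expect_equal(unique(st$truth$load$f_j_pct_bw), 67)
})

test_that("simulate_study writes pipeline-readable files plus truth sidecar", {
  cfg <- fast_config(seed = 10, n_subjects = 1, emg_sampling_rate = 50)
  dir <- withr::local_tempdir()
  simulate_study(cfg, dir)
  sd <- file.path(dir, "S01")
  expect_true(all(file.exists(file.path(sd, c(
    "subject.txt", "rest.csv", "vct_30_1.csv", "vct_60_3.csv",
    "rest_sweep_60.csv", "slss.csv", "ground_truth.json")))))
  subj <- read_subject_file(file.path(sd, "subject.txt"))
  orig <- generate_subject(cfg, 1)
  expect_equal(subj$mass, orig$subject$mass, tolerance = 1e-9)
  vct <- read_vct_csv(file.path(sd, "vct_60_1.csv"))
  expect_equal(vct$speed, 60)
  expect_equal(vct$torque, generate_vct(orig, cfg, 60, 1)$torque,
               tolerance = 1e-9)
  task <- read_task_csv(file.path(sd, "slss.csv"), subj)
  expect_s3_class(task, "task_trial")
  rest <- read_rest_csv(file.path(sd, "rest.csv"))
  expect_equal(rest[["LEO"]]$samples,
               generate_rest_trial(orig, cfg)[["LEO"]]$samples,
               tolerance = 1e-9)
})
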