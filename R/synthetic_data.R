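# Deterministic sub-seed derivation: every generated artifact draws from a
# seed mixed from (config seed, subject index, trial tag), so output is
# reproducible per id regardless of call order. Arithmetic stays exact in
# doubles (operands < 2^53).
mix_seed <- function(...) {
  ids <- c(...)
  h <- 0
  for (v in ids) h <- (h * 48271 + (abs(v) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rtruncnorm1 <- function(mu, sd, lo, hi) {
  if (lo > hi) stop("invalid range")
  if (lo == hi || sd <= 0) return(max(min(mu, hi), lo))
  stats::qnorm(stats::runif(1, stats::pnorm(lo, mu, sd),
                            stats::pnorm(hi, mu, sd)), mu, sd)
}

#' Configuration for the synthetic motion-lab study
#'
#' Defines the conditions the generator emulates: a cohort of young male
#' subjects (BMI mean 25.2, SD 0.8), 5 s supine rest recordings,
#' three-cycle concentric flexion/extension voluntary-contraction trials at
#' 30 and 60 deg/s (one maximum-effort trial and two sub-maximal trials per
#' speed), and 30 s straight-leg stoop-to-stand bouts lifting an 8 kg ball
#' with 2 s upright holds. EMG is synthesised at the envelope level;
#' sampling rates default to 2000 Hz (EMG) and 100 Hz (kinematics).
#'
#' @param seed Master seed; identical (config, ids) give identical output.
#' @param n_subjects Number of subjects in the cohort.
#' @param emg_sampling_rate EMG/envelope sampling rate, Hz.
#' @param kinematic_sampling_rate Kinematic sampling rate, Hz.
#' @param noise_sd Envelope noise SD (envelope units; unit-maximum scale).
#' @param baseline_offset DC offset of raw rest traces (raw signal units).
#' @param vct_speeds Isokinetic speeds, deg/s.
#' @param vct_angle_range Lever-angle range of the VCT, degrees.
#' @param effort_levels Per-trial effort levels for the three VCTs per speed.
#' @param n_lifts Lift cycles per stoop-to-stand bout.
#' @param task_duration Bout duration, s.
#' @param ball_mass Lifted ball mass, kg.
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (truncated normal).
#' @param gain_spread Inter-subject multiplicative spread of relationship
#'   gains (subject gains are drawn uniformly on `[1, gain_spread]`).
#' @param shape_spread Inter-subject spread of relationship shape (intercept
#'   fraction / log-slope factors), driving specific-vs-general differences.
#' @param coefficient_table Anthropometric coefficient table shared with the
#'   analysis pipeline.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_subjects = 8L,
                             emg_sampling_rate = 2000,
                             kinematic_sampling_rate = 100,
                             noise_sd = 0.02, baseline_offset = 0.5,
                             vct_speeds = c(30, 60),
                             vct_angle_range = c(0, 90),
                             effort_levels = c(1, 0.7, 0.4),
                             n_lifts = 3L, task_duration = 30,
                             ball_mass = 8,
                             bmi_mean = 25.2, bmi_sd = 0.8,
                             bmi_range = c(20, 30),
                             gain_spread = 2.5, shape_spread = 1.4,
                             coefficient_table = default_coefficient_table()) {
  stopifnot(emg_sampling_rate > 0, kinematic_sampling_rate > 0,
            noise_sd >= 0, n_subjects >= 1, all(vct_speeds > 0),
            diff(vct_angle_range) > 0, all(effort_levels >= 0),
            n_lifts >= 1, task_duration > 0, ball_mass > 0,
            gain_spread >= 1, shape_spread >= 1)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 emg_sampling_rate = emg_sampling_rate,
                 kinematic_sampling_rate = kinematic_sampling_rate,
                 noise_sd = noise_sd, baseline_offset = baseline_offset,
                 vct_speeds = vct_speeds, vct_angle_range = vct_angle_range,
                 effort_levels = effort_levels, n_lifts = as.integer(n_lifts),
                 task_duration = task_duration, ball_mass = ball_mass,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
                 gain_spread = gain_spread, shape_spread = shape_spread,
                 coefficient_table = coefficient_table),
            class = "synthetic_config")
}

#' Generate a synthetic subject with ground truth
#'
#' Draws anthropometry (BMI from a truncated normal, stature around 1.78 m,
#' torso and leg dimensions geometrically consistent with stature) and the
#' subject's true force-to-sEMG relationships: linear `F = a + b*s` for the
#' erector spinae and logarithmic `F = a + b*ln(s)` for rectus abdominis and
#' external obliques, with per-subject gain and shape variation. Muscle
#' geometry is derived with the same coefficient table the analysis pipeline
#' uses, so calibration round trips are exact. The ground truth also fixes
#' the subject's dynamometer gravity-artifact curve: a cubic in lever angle,
#' deliberately not proportional to `sin(angle)` (the torso weight actually
#' borne by the lever does not follow the weight-times-sine assumption).
#'
#' @param config A [synthetic_config()].
#' @param index Subject index in `1..n_subjects`.
#' @return An object of class `synthetic_subject`: list with `subject` (a
#'   [subject_record()]) and `truth` (relationships, annotated geometry,
#'   CSA ratio, gravity-curve coefficients). The truth component is never
#'   read by the analysis pipeline.
#' @export
generate_subject <- function(config, index) {
  stopifnot(inherits(config, "synthetic_config"))
  index <- as.integer(index)
  if (index < 1 || index > config$n_subjects)
    stop("subject index out of range 1..n_subjects")
  with_seed(mix_seed(config$seed, 1L, index), {
    height <- rtruncnorm1(1.78, 0.06, 1.60, 2.00)
    bmi <- rtruncnorm1(config$bmi_mean, config$bmi_sd,
                       config$bmi_range[1], config$bmi_range[2])
    mass <- bmi * height^2
    subj <- subject_record(
      mass = mass, height = height,
      torso_depth = 0.115 * height * stats::runif(1, 0.95, 1.05),
      torso_width = 0.170 * height * stats::runif(1, 0.95, 1.05),
      leg_length = 0.530 * height * stats::runif(1, 0.97, 1.03),
      id = sprintf("S%02d", index))
    geom <- estimate_muscle_geometry(subj, config$coefficient_table)
    geom <- muscle_angles(geom, subj$lever_arm_length)
    r <- geom$csa[geom$muscle == "EO"] / geom$csa[geom$muscle == "RA"]
    gain <- stats::runif(3, 1, config$gain_spread)  # ES, RA, EO
    alpha_es <- stats::runif(1, 0.05, 0.30)
    sh <- stats::runif(2, 1 / config$shape_spread, config$shape_spread)
    fmax_es <- 1500 * gain[1]   # per-side N at unit envelope
    fmax_ra <- 600 * gain[2]
    rel <- list(
      ES = list(form = "linear", a = alpha_es * fmax_es,
                b = (1 - alpha_es) * fmax_es),
      RA = list(form = "logarithmic", a = fmax_ra, b = 200 * sh[1]),
      EO = list(form = "logarithmic", a = r * fmax_ra, b = 280 * sh[2]))
    grav <- list(amplitude = 0.12 * mass * GRAVITY * stats::runif(1, 0.9, 1.1),
                 c1 = 1.05 * stats::runif(1, 0.95, 1.05),
                 c2 = 0.35 * stats::runif(1, 0.95, 1.05),
                 c3 = -0.55 * stats::runif(1, 0.95, 1.05),
                 angle_scale = config$vct_angle_range[2])
    structure(list(subject = subj,
                   truth = list(relationships = rel, geometry = geom,
                                csa_ratio = r, gravity = grav,
                                index = index)),
              class = "synthetic_subject")
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat("<synthetic_subject>\n  ")
  print(x$subject)
  rel <- x$truth$relationships
  for (m in names(rel))
    cat(sprintf("  true %s: %s a = %.1f, b = %.1f\n", m, rel[[m]]$form,
                rel[[m]]$a, rel[[m]]$b))
  invisible(x)
}

# True gravity-artifact torque (N*m) as a function of lever angle (deg).
gravity_artifact <- function(truth, angle) {
  g <- truth$gravity
  x <- angle / g$angle_scale
  g$amplitude * (g$c1 * x + g$c2 * x^2 + g$c3 * x^3)
}

# Evaluate a true relationship: force (per side, N) from envelope.
true_force <- function(rel, env) {
  if (rel$form == "linear") pmax(rel$a + rel$b * env, 0)
  else {
    out <- numeric(length(env))
    pos <- env > 0
    out[pos] <- pmax(rel$a + rel$b * log(env[pos]), 0)
    out
  }
}

# Envelope at which a logarithmic relationship crosses zero force.
log_zero_envelope <- function(rel) exp(-rel$a / rel$b)

#' Generate a supine rest trial
#'
#' Six channels of raw baseline: DC offset plus zero-mean Gaussian carrier
#' noise, recorded for `duration_s` (default 5 s) at the EMG rate.
#'
#' @param synth A [generate_subject()] result.
#' @param config The [synthetic_config()].
#' @param duration_s Duration, s.
#' @return Named list of [emg_trace()] objects, one per channel.
#' @export
generate_rest_trial <- function(synth, config, duration_s = 5) {
  stopifnot(inherits(synth, "synthetic_subject"), duration_s > 0)
  n <- round(duration_s * config$emg_sampling_rate)
  with_seed(mix_seed(config$seed, 2L, synth$truth$index), {
    out <- lapply(EMG_CHANNELS, function(ch)
      emg_trace(config$baseline_offset +
                  stats::rnorm(n, 0, config$noise_sd),
                config$emg_sampling_rate, ch, "rest"))
    names(out) <- EMG_CHANNELS
    out
  })
}

# Triangle-wave lever angle over 3 cycles; returns the folded index k so
# every visited angle lies exactly on the up-sweep grid a0 + speed*k/rate.
vct_angle_grid <- function(config, speed) {
  rate <- config$emg_sampling_rate
  a0 <- config$vct_angle_range[1]; a1 <- config$vct_angle_range[2]
  n_half <- max(2L, round((a1 - a0) / speed * rate))
  i <- 0:(6L * n_half - 1L)
  m <- i %% (2L * n_half)
  k <- ifelse(m <= n_half, m, 2L * n_half - m)
  list(time = i / rate, k = k, n_half = n_half,
       angle = a0 + speed * k / rate,
       frac = (m %% n_half + (m == n_half) * n_half) / n_half,
       rising = m < n_half, cycle = pmin(i %/% (2L * n_half) + 1L, 3L))
}

#' Generate a voluntary-contraction trial
#'
#' Builds a three-cycle concentric flexion/extension trial at the requested
#' isokinetic speed. The lever angle is a triangle wave; the recorded torque
#' is the subject's gravity-artifact curve plus the muscle moment
#' forward-computed through the same moment balances the calibration stage
#' solves (rising angle = flexion, driven by RA and EO with the equal-stress
#' CSA-ratio split; falling angle = extension, driven by the ES). Channel
#' envelopes follow the inverse of the subject's true relationships, with
#' optional additive noise, so noise-free trials round-trip the ground-truth
#' coefficients through the pipeline to machine precision. A zero-effort
#' rest sweep over one full cycle at the same angles is attached for gravity
#' calibration.
#'
#' @param synth A [generate_subject()] result.
#' @param config The [synthetic_config()].
#' @param speed Speed, deg/s; must be one of `config$vct_speeds`.
#' @param effort Effort level(s) in `[0, 1]`: scalar, or one value per cycle
#'   (length 3).
#' @param trial_id Integer distinguishing repeated trials at one speed.
#' @return A [vct_trial()] with extra fields `rest_sweep` (angle/torque of
#'   the relaxed sweep) and `truth` (per-sample true group forces and
#'   activation), which the pipeline never reads.
#' @export
generate_vct <- function(synth, config, speed, effort = 1, trial_id = 1L) {
  stopifnot(inherits(synth, "synthetic_subject"))
  if (!speed %in% config$vct_speeds)
    stop("speed ", speed, " not in configured vct_speeds")
  if (any(effort < 0 | effort > 1)) stop("effort must lie in [0, 1]")
  effort <- rep_len(effort, 3L)
  truth <- synth$truth
  subj <- synth$subject
  grid <- vct_angle_grid(config, speed)
  n <- length(grid$time)
  act <- effort[grid$cycle] * sinpi(grid$frac)
  act[grid$frac %in% c(0, 1)] <- 0
  rel <- truth$relationships
  geom <- truth$geometry
  g <- function(m) geom[geom$muscle == m, ]
  flex <- grid$rising & act > 0
  ext <- (!grid$rising) & act > 0
  env_es <- ifelse(ext, act, 0)
  f_es <- ifelse(ext, true_force(rel$ES, env_es), 0)
  s0_ra <- log_zero_envelope(rel$RA)
  env_ra <- ifelse(flex, s0_ra + (1 - s0_ra) * act, s0_ra)
  f_ra <- ifelse(flex, true_force(rel$RA, env_ra), 0)
  f_eo <- truth$csa_ratio * f_ra
  env_eo <- exp((f_eo - rel$EO$a) / rel$EO$b)
  torque <- gravity_artifact(truth, grid$angle) +
    2 * f_es * g("ES")$moment_arm * cospi(g("ES")$inclination / 180) -
    2 * (f_ra * g("RA")$moment_arm * cospi(g("RA")$inclination / 180) +
           f_eo * g("EO")$moment_arm * cospi(45 / 180))
  env_true <- cbind(RES = env_es, LES = env_es, RRA = env_ra, LRA = env_ra,
                    REO = env_eo, LEO = env_eo)
  env <- with_seed(mix_seed(config$seed, 3L, truth$index,
                            round(speed), trial_id), {
    if (config$noise_sd > 0)
      pmax(env_true + matrix(stats::rnorm(n * 6, 0, config$noise_sd), n, 6),
           0)
    else env_true
  })
  colnames(env) <- EMG_CHANNELS
  rest_k <- c(0:grid$n_half, (grid$n_half - 1):0)
  rest_angle <- config$vct_angle_range[1] +
    speed * rest_k / config$emg_sampling_rate
  trial <- vct_trial(grid$time, grid$angle, torque, env, speed,
                     subj$lever_arm_length)
  trial$rest_sweep <- list(angle = rest_angle,
                           torque = gravity_artifact(truth, rest_angle))
  trial$truth <- list(f_es = 2 * f_es, f_ra = 2 * f_ra, f_eo = 2 * f_eo,
                      activation = act, envelopes = env_true,
                      gravity_torque = gravity_artifact(truth, grid$angle))
  trial
}

#' Generate the full set of VCTs for one subject
#'
#' One trial per effort level per configured speed (default: maximum effort
#' plus two sub-maximal trials at 30 and at 60 deg/s).
#'
#' @param synth A [generate_subject()] result.
#' @param config The [synthetic_config()].
#' @return List of [generate_vct()] trials.
#' @export
generate_vct_set <- function(synth, config) {
  out <- list()
  for (sp in config$vct_speeds)
    for (k in seq_along(config$effort_levels))
      out[[sprintf("vct_%g_%d", sp, k)]] <-
        generate_vct(synth, config, sp, config$effort_levels[k], trial_id = k)
  out
}

# Smoothstep ramp used for torso inclination profiles.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Generate a straight-leg stoop-to-stand trial
#'
#' Emulates one bout: the torso cycles between upright (0 deg) and a flexed
#' inclination with 2 s upright holds while the ball is lifted from the
#' floor, carried up, held, and replaced — the ball-height channel rises
#' above the floor exactly `n_lifts` times. Channel envelopes follow
#' prescribed activation profiles through the subject's true relationships
#' (plus optional noise); the true per-channel forces and the true L4/L5
#' load series (through the vertical force balance) are stored for recovery
#' tests.
#'
#' @param synth A [generate_subject()] result.
#' @param config The [synthetic_config()].
#' @param n_lifts Number of lift cycles (default from config).
#' @param flexed_angle Torso inclination when stooped, degrees.
#' @return A [task_trial()] with extra field `truth` (true forces, true
#'   load series, true envelopes, carry flag and lift boundary times).
#' @export
generate_slss_trial <- function(synth, config, n_lifts = config$n_lifts,
                                flexed_angle = 75) {
  stopifnot(inherits(synth, "synthetic_subject"), n_lifts >= 1)
  truth <- synth$truth
  subj <- synth$subject
  L <- config$task_duration / n_lifts
  if (0.7 * L + 2 > L)
    stop("task_duration too short for ", n_lifts,
         " lifts with 2 s upright holds")
  rate <- config$emg_sampling_rate
  n <- round(config$task_duration * rate) + 1L
  t <- (seq_len(n) - 1) / rate
  tc <- t %% L                      # time within the lift cycle
  d <- 0.15 * L; dg <- 0.05 * L     # ramp and grab/release durations
  # piecewise torso inclination: stoop, grab, rise, 2 s hold, stoop,
  # release, rise, stand
  b <- cumsum(c(0, d, dg, d, 2, d, dg, d))  # segment boundaries
  theta <- numeric(n)
  seg <- findInterval(tc, b, rightmost.closed = FALSE)
  u <- (tc - b[pmax(seg, 1)])
  theta[seg == 1] <- flexed_angle * smoothstep(u[seg == 1] / d)
  theta[seg == 2] <- flexed_angle
  theta[seg == 3] <- flexed_angle * (1 - smoothstep(u[seg == 3] / d))
  theta[seg == 4] <- 0
  theta[seg == 5] <- flexed_angle * smoothstep(u[seg == 5] / d)
  theta[seg == 6] <- flexed_angle
  theta[seg == 7] <- flexed_angle * (1 - smoothstep(u[seg == 7] / d))
  theta[seg >= 8] <- 0
  carrying <- seg %in% 3:5          # grabbed at end of seg 2, replaced at 6
  h0 <- 0.10; h_top <- 1.00
  ball <- rep(h0, n)
  ball[carrying] <- h0 + (h_top - h0) * (1 - theta[carrying] / flexed_angle)
  sin_ratio <- sinpi(theta / 180) / sinpi(flexed_angle / 180)
  act_es <- 0.15 + (0.70 + 0.15 * carrying) * sin_ratio
  act_ra <- 0.10 + 0.06 * sin_ratio
  act_eo <- 0.10 + 0.08 * carrying
  rel <- truth$relationships
  s0_ra <- log_zero_envelope(rel$RA); s0_eo <- log_zero_envelope(rel$EO)
  env_true <- cbind(RES = act_es, LES = act_es,
                    RRA = s0_ra + (1 - s0_ra) * act_ra,
                    LRA = s0_ra + (1 - s0_ra) * act_ra,
                    REO = s0_eo + (1 - s0_eo) * act_eo,
                    LEO = s0_eo + (1 - s0_eo) * act_eo)
  forces <- lapply(EMG_CHANNELS, function(ch)
    true_force(rel[[EMG_CHANNEL_GROUPS[[ch]]]], env_true[, ch]))
  names(forces) <- EMG_CHANNELS
  true_load <- compute_load_series(forces, truth$geometry, subj, theta, t)
  env <- with_seed(mix_seed(config$seed, 4L, truth$index, n_lifts), {
    if (config$noise_sd > 0)
      pmax(env_true + matrix(stats::rnorm(n * 6, 0, config$noise_sd), n, 6),
           0)
    else env_true
  })
  colnames(env) <- EMG_CHANNELS
  trial <- task_trial(t, env, theta, ball, subj)
  trial$truth <- list(forces = forces, load = true_load,
                      envelopes = env_true, carrying = carrying,
                      n_lifts = as.integer(n_lifts))
  trial
}

#' Generate a quiet standing trial
#'
#' Degenerate task trial used for analytic checks: vertical torso
#' throughout, all envelopes at zero (at or below any rest level), ball on
#' the floor. Under the vertical force balance the true compressive load is
#' exactly 67% of body weight at every sample.
#'
#' @param synth A [generate_subject()] result.
#' @param config The [synthetic_config()].
#' @param duration_s Duration, s.
#' @return A [task_trial()] with `truth$load` attached.
#' @export
generate_standing_trial <- function(synth, config, duration_s = 5) {
  subj <- synth$subject
  n <- round(duration_s * config$emg_sampling_rate) + 1L
  t <- (seq_len(n) - 1) / config$emg_sampling_rate
  env <- matrix(0, n, 6, dimnames = list(NULL, EMG_CHANNELS))
  forces <- stats::setNames(rep(list(rep(0, n)), 6), EMG_CHANNELS)
  theta <- rep(0, n)
  trial <- task_trial(t, env, theta, rep(0.10, n), subj)
  trial$truth <- list(forces = forces,
                      load = compute_load_series(forces,
                                                 synth$truth$geometry,
                                                 subj, theta, t))
  trial
}
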