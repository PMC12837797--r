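#' Construct a voluntary-contraction trial
#'
#' A synchronized isokinetic dynamometer recording: lever-arm angle and raw
#' torque on a common timebase with the six trunk sEMG envelopes.
#'
#' @param time Time vector, s (uniform grid).
#' @param lever_angle Lever-arm angle, degrees.
#' @param torque Raw dynamometer torque, N·m (uncorrected for torso weight).
#' @param envelopes Named list of `emg_envelope` objects (one per channel in
#'   [EMG_CHANNELS]) or a numeric matrix with those column names, on the same
#'   timebase as `time`.
#' @param speed Nominal contraction speed, deg/s.
#' @param lever_arm_length Lever-arm length d_L, m.
#' @return An object of class `vct_trial`.
#' @export
vct_trial <- function(time, lever_angle, torque, envelopes, speed,
                      lever_arm_length) {
  n <- length(time)
  if (length(lever_angle) != n || length(torque) != n)
    stop("time, lever_angle and torque must share a timebase")
  env <- as_envelope_matrix(envelopes, n)
  structure(list(time = time, lever_angle = lever_angle, torque = torque,
                 envelopes = env, speed = speed,
                 lever_arm_length = lever_arm_length),
            class = "vct_trial")
}

as_envelope_matrix <- function(envelopes, n) {
  if (is.list(envelopes) && !is.data.frame(envelopes)) {
    stopifnot(all(EMG_CHANNELS %in% names(envelopes)))
    env <- sapply(EMG_CHANNELS, function(ch) envelopes[[ch]]$samples)
  } else {
    env <- as.matrix(envelopes)
    stopifnot(all(EMG_CHANNELS %in% colnames(env)))
    env <- env[, EMG_CHANNELS, drop = FALSE]
  }
  if (nrow(env) != n) stop("envelopes not on the trial timebase")
  env
}

#' @export
print.vct_trial <- function(x, ...) {
  cat(sprintf("<vct_trial> %g deg/s: %d samples over %.2f s, angle [%g, %g] deg\n",
              x$speed, length(x$time), diff(range(x$time)),
              min(x$lever_angle), max(x$lever_angle)))
  invisible(x)
}

#' Fit the dynamometer gravity-artifact calibration curve
#'
#' The torso's weight on the lever arm contributes an angle-dependent torque
#' that must be removed before attributing the measured moment to muscle
#' effort. A rest sweep (subject relaxed, lever moving through its range)
#' records that artifact; this fits a piecewise-linear interpolant of rest
#' torque versus lever angle. The shape is measured, not assumed: a
#' weight-times-sine model does not match the torso weight actually borne by
#' the dynamometer. Queries outside the measured range clamp to the endpoint
#' values.
#'
#' @param angle Lever angles of the rest sweep, degrees (>= 2 distinct).
#' @param torque Rest torque at those angles, N·m.
#' @return Object of class `gravity_calibration`; evaluate with `predict()`.
#' @export
fit_gravity_calibration <- function(angle, torque) {
  stopifnot(length(angle) == length(torque))
  ok <- is.finite(angle) & is.finite(torque)
  angle <- angle[ok]; torque <- torque[ok]
  # collapse repeated angles (the artifact is a function of angle only)
  grid <- sort(unique(angle))
  if (length(grid) < 2) stop("need >= 2 distinct angles for calibration")
  tq <- vapply(grid, function(a) mean(torque[angle == a]), numeric(1))
  structure(list(angle = grid, torque = tq), class = "gravity_calibration")
}

#' @export
predict.gravity_calibration <- function(object, angle, ...) {
  stats::approx(object$angle, object$torque, xout = angle, rule = 2)$y
}

#' @export
print.gravity_calibration <- function(x, ...) {
  cat(sprintf("<gravity_calibration> %d nodes over [%g, %g] deg, torque [%g, %g] N·m\n",
              length(x$angle), min(x$angle), max(x$angle),
              min(x$torque), max(x$torque)))
  invisible(x)
}

#' Gravity-correct the measured moment
#'
#' Subtracts the rest-sweep calibration curve from the raw torque and
#' divides by the lever-arm length, yielding the torso-weight-corrected
#' moment M_B* expressed as the equivalent resistive force at the lever-arm
#' pad (N). With that convention `M_B* * d_L` is the external moment in N·m
#' and the printed moment balances are dimensionally consistent.
#'
#' @param raw_torque Raw dynamometer torque, N·m.
#' @param angle Concurrent lever angle, degrees.
#' @param curve A [fit_gravity_calibration()] result.
#' @param lever_arm_length Lever-arm length d_L, m.
#' @return Numeric vector: corrected moment as pad force, N.
#' @export
correct_moment <- function(raw_torque, angle, curve, lever_arm_length) {
  stopifnot(inherits(curve, "gravity_calibration"),
            length(raw_torque) == length(angle))
  if (lever_arm_length <= 0) stop("lever_arm_length must be > 0")
  (raw_torque - predict(curve, angle)) / lever_arm_length
}

#' Label flexion / extension phases from the lever-angle trajectory
#'
#' Phase is the sign of the lever angular velocity (central differences):
#' increasing angle is flexion, decreasing is extension. Samples with
#' |velocity| inside a deadband (default 2 deg/s) sit at direction reversals
#' and are labelled `"none"`; they are excluded from calibration.
#'
#' @param lever_angle Lever angle, degrees.
#' @param sampling_rate Hz.
#' @param deadband Velocity deadband, deg/s.
#' @return Character vector (`"flexion"`, `"extension"`, `"none"`).
#' @export
label_phases <- function(lever_angle, sampling_rate, deadband = 2) {
  n <- length(lever_angle)
  if (n < 2) return(rep("none", n))
  v <- numeric(n)
  v[2:(n - 1)] <- (lever_angle[3:n] - lever_angle[1:(n - 2)]) *
    sampling_rate / 2
  v[1] <- (lever_angle[2] - lever_angle[1]) * sampling_rate
  v[n] <- (lever_angle[n] - lever_angle[n - 1]) * sampling_rate
  out <- rep("none", n)
  out[v > deadband] <- "flexion"
  out[v < -deadband] <- "extension"
  out
}

#' Solve the extension moment balance for the erector spinae force
#'
#' During extension the corrected external moment is attributed entirely to
#' the erector spinae: `M_B* * d_L = F_ES * d_ES * cos(theta_ES)`. Negative
#' solutions (moment opposing extension) are clamped to zero.
#'
#' @param mbstar Corrected moment as pad force (N), extension-phase samples.
#' @param lever_arm_length d_L, m.
#' @param d_es ES moment arm, m.
#' @param theta_es ES inclination, degrees.
#' @return List with `total` (group force, N) and `per_side` (= total / 2).
#' @export
solve_extension_force <- function(mbstar, lever_arm_length, d_es, theta_es) {
  den <- d_es * cospi(theta_es / 180)
  if (!is.finite(den) || den <= 0)
    stop("degenerate ES geometry: d_ES * cos(theta_ES) must be > 0")
  f <- pmax(mbstar * lever_arm_length / den, 0)
  list(total = f, per_side = f / 2)
}

#' Solve the flexion moment balance for abdominal forces
#'
#' During flexion the corrected moment is shared by rectus abdominis and
#' external obliques: `M_B* * d_L = F_RA * d_RA * cos(theta_RA) + F_EO *
#' d_EO * cos(45°)`. One equation, two unknowns; the indeterminacy is closed
#' with the equal-stress assumption `F_EO = r * F_RA`, where `r` is the
#' EO-to-RA cross-sectional-area ratio. Negative solutions are clamped to
#' zero.
#'
#' @param mbstar Corrected moment as pad force (N), flexion-phase samples
#'   (flexor moment positive).
#' @param lever_arm_length d_L, m.
#' @param d_ra,theta_ra RA moment arm (m) and inclination (deg).
#' @param d_eo EO moment arm, m (EO crossing angle is fixed at 45 deg).
#' @param csa_ratio r = CSA_EO / CSA_RA (> 0; 0 attributes everything to RA).
#' @return List with `ra_total`, `eo_total`, `ra_per_side`, `eo_per_side` (N).
#' @export
solve_flexion_forces <- function(mbstar, lever_arm_length, d_ra, theta_ra,
                                 d_eo, csa_ratio) {
  if (csa_ratio < 0) stop("csa_ratio must be >= 0")
  den <- d_ra * cospi(theta_ra / 180) + csa_ratio * d_eo * cospi(45 / 180)
  if (!is.finite(den) || den <= 0)
    stop("degenerate flexion geometry: moment denominator must be > 0")
  f_ra <- pmax(mbstar * lever_arm_length / den, 0)
  f_eo <- csa_ratio * f_ra
  list(ra_total = f_ra, eo_total = f_eo,
       ra_per_side = f_ra / 2, eo_per_side = f_eo / 2)
}

#' Solve muscle forces for a whole voluntary-contraction trial
#'
#' Gravity-corrects the trial's torque, labels phases, and routes each
#' sample to the appropriate moment balance: extension-phase samples to the
#' ES balance (extensor moment taken positive), flexion-phase samples to the
#' RA/EO balance (flexor moment is the negated corrected moment). Samples in
#' the velocity deadband get zero force and phase `"none"`.
#'
#' @param trial A [vct_trial()].
#' @param curve A [fit_gravity_calibration()] result for the same subject.
#' @param geometry A [muscle_angles()]-annotated geometry table.
#' @param deadband Phase-labelling velocity deadband, deg/s.
#' @return A list with per-sample vectors `phase`, `mbstar`, and group
#'   forces `f_es`, `f_ra`, `f_eo` (N, total over both sides).
#' @export
solve_vct_forces <- function(trial, curve, geometry, deadband = 2) {
  stopifnot(inherits(trial, "vct_trial"))
  rate <- 1 / mean(diff(trial$time))
  phase <- label_phases(trial$lever_angle, rate, deadband)
  mb <- correct_moment(trial$torque, trial$lever_angle, curve,
                       trial$lever_arm_length)
  g <- function(m) geometry[geometry$muscle == m, ]
  es <- g("ES"); ra <- g("RA"); eo <- g("EO")
  r <- eo$csa / ra$csa
  n <- length(mb)
  f_es <- f_ra <- f_eo <- numeric(n)
  ext <- phase == "extension"
  fle <- phase == "flexion"
  f_es[ext] <- solve_extension_force(mb[ext], trial$lever_arm_length,
                                     es$moment_arm, es$inclination)$total
  fl <- solve_flexion_forces(-mb[fle], trial$lever_arm_length,
                             ra$moment_arm, ra$inclination,
                             eo$moment_arm, r)
  f_ra[fle] <- fl$ra_total
  f_eo[fle] <- fl$eo_total
  list(phase = phase, mbstar = mb, f_es = f_es, f_ra = f_ra, f_eo = f_eo)
}

#' Pair solved muscle forces with concurrent sEMG envelopes
#'
#' Builds the per-muscle calibration samples: extension-phase samples feed
#' the two ES channels, flexion-phase samples the RA and EO channels. Each
#' channel is paired with half the solved group force (bilateral forces are
#' equal) and its own side's envelope. Samples in the velocity deadband, and
#' samples whose envelope is below the channel's rest level, are excluded.
#'
#' @param trial A [vct_trial()].
#' @param forces A [solve_vct_forces()] result for the same trial.
#' @param baselines Named list of `rest_baseline` objects (one per channel);
#'   `NULL` skips rest-threshold exclusion.
#' @return A data.frame of class `force_emg_samples` with columns `muscle`,
#'   `force` (N, per side), `envelope`, `speed`, `phase`.
#' @export
pair_force_emg <- function(trial, forces, baselines = NULL) {
  stopifnot(inherits(trial, "vct_trial"))
  if (length(forces$phase) != nrow(trial$envelopes))
    stop("forces and envelopes are not on a common timebase")
  out <- list()
  for (ch in EMG_CHANNELS) {
    grp <- EMG_CHANNEL_GROUPS[[ch]]
    keep <- if (grp == "ES") forces$phase == "extension"
            else forces$phase == "flexion"
    f_side <- switch(grp, ES = forces$f_es, RA = forces$f_ra,
                     EO = forces$f_eo) / 2
    env <- trial$envelopes[, ch]
    if (!is.null(baselines)) {
      lev <- baselines[[ch]]$rest_envelope_level
      keep <- keep & env >= lev
    }
    if (any(keep)) {
      out[[ch]] <- data.frame(muscle = ch, force = f_side[keep],
                              envelope = env[keep], speed = trial$speed,
                              phase = forces$phase[keep],
                              stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(muscle = character(0), force = numeric(0),
               envelope = numeric(0), speed = numeric(0),
               phase = character(0))
  rownames(res) <- NULL
  class(res) <- c("force_emg_samples", "data.frame")
  res
}

#' Calibrate force-to-sEMG relationships from a set of VCTs
#'
#' Runs the full calibration for one subject: solves muscle forces for every
#' trial, pools the force-envelope pairs per channel and speed, and fits the
#' requested relationship forms.
#'
#' @param trials List of [vct_trial()] objects (all speeds, all efforts).
#' @param curve Gravity calibration for this subject.
#' @param geometry [muscle_angles()]-annotated geometry.
#' @param baselines Named list of `rest_baseline` objects, or `NULL`.
#' @param forms Relationship forms to fit (default both).
#' @param deadband Phase deadband, deg/s.
#' @return A list of class `calibration_set`: `samples` (pooled
#'   `force_emg_samples`), `fits` (nested list `fits[[speed]][[form]][[muscle]]`
#'   of [force_emg] objects), `speeds`.
#' @export
calibrate_relationships <- function(trials, curve, geometry, baselines = NULL,
                                    forms = c("linear", "logarithmic"),
                                    deadband = 2) {
  samples <- do.call(rbind, lapply(trials, function(tr) {
    pair_force_emg(tr, solve_vct_forces(tr, curve, geometry, deadband),
                   baselines)
  }))
  class(samples) <- c("force_emg_samples", "data.frame")
  speeds <- sort(unique(samples$speed))
  fits <- list()
  for (sp in speeds) {
    key <- as.character(sp)
    fits[[key]] <- list()
    for (form in forms) {
      fits[[key]][[form]] <- list()
      for (ch in EMG_CHANNELS) {
        sub <- samples[samples$muscle == ch & samples$speed == sp, ]
        if (nrow(sub) >= 3) {
          fits[[key]][[form]][[ch]] <- fit_force_emg(
            sub$force, sub$envelope, form = form, muscle = ch, speed = sp)
        }
      }
    }
  }
  structure(list(samples = samples, fits = fits, speeds = speeds),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("<calibration_set> %d samples, speeds: %s deg/s\n",
              nrow(x$samples), paste(x$speeds, collapse = ", ")))
  invisible(x)
}
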