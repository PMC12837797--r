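#' Construct a lifting-task trial
#'
#' A stoop-to-stand recording: the six sEMG envelopes, torso inclination and
#' ball-marker height on a common timebase.
#'
#' @param time Time vector, s (uniform grid).
#' @param envelopes Named list of `emg_envelope` objects or matrix with
#'   columns [EMG_CHANNELS].
#' @param torso_angle Torso inclination from vertical, degrees (0 = upright).
#' @param ball_height Ball-marker height, m.
#' @param subject The [subject_record()] the trial belongs to.
#' @return An object of class `task_trial`.
#' @export
task_trial <- function(time, envelopes, torso_angle, ball_height, subject) {
  n <- length(time)
  if (length(torso_angle) != n || length(ball_height) != n)
    stop("time, torso_angle and ball_height must share a timebase")
  if (any(torso_angle < 0 | torso_angle > 120))
    stop("torso_angle must lie in [0, 120] degrees from vertical")
  env <- as_envelope_matrix(envelopes, n)
  structure(list(time = time, envelopes = env, torso_angle = torso_angle,
                 ball_height = ball_height, subject = subject),
            class = "task_trial")
}

#' @export
print.task_trial <- function(x, ...) {
  cat(sprintf("<task_trial> %d samples over %.1f s, torso angle [%g, %g] deg\n",
              length(x$time), diff(range(x$time)),
              min(x$torso_angle), max(x$torso_angle)))
  invisible(x)
}

#' Torso inclination from sacrum and sternum markers
#'
#' Angle between the sacrum-to-sternum vector and the vertical (z) axis, in
#' degrees. 0 is upright.
#'
#' @param sacrum,sternum Numeric matrices (n x 3) of marker positions, or
#'   length-3 vectors for a single frame.
#' @return Numeric vector of angles, degrees.
#' @export
torso_angle_from_markers <- function(sacrum, sternum) {
  if (is.null(dim(sacrum))) sacrum <- matrix(sacrum, nrow = 1)
  if (is.null(dim(sternum))) sternum <- matrix(sternum, nrow = 1)
  v <- sternum - sacrum
  len <- sqrt(rowSums(v^2))
  if (any(len == 0)) stop("zero-length sacrum-to-sternum vector")
  unname(acos(pmin(pmax(v[, 3] / len, -1), 1)) * 180 / pi)
}

#' Predict a muscle-force series from a task-trial envelope
#'
#' Applies a calibrated relationship to an envelope, after zeroing samples
#' below the channel's rest level (sub-rest activity carries no force
#' information). Predictions are clamped at zero; general relationships
#' rescale through the subject's own calibration maxima.
#'
#' @param relationship A [force_emg] fit for this channel.
#' @param envelope An `emg_envelope` (or numeric vector).
#' @param baseline A `rest_baseline` for the channel, or `NULL` to skip the
#'   rest threshold.
#' @param max_force,max_envelope Subject maxima (general relationships only).
#' @return Numeric force series, N (per side).
#' @export
predict_muscle_force <- function(relationship, envelope, baseline = NULL,
                                 max_force = NULL, max_envelope = NULL) {
  stopifnot(inherits(relationship, "force_emg"))
  samples <- if (inherits(envelope, "emg_envelope")) envelope$samples
             else as.numeric(envelope)
  if (inherits(envelope, "emg_envelope") && !is.null(baseline) &&
      envelope$channel != baseline$channel)
    stop("channel mismatch between envelope and baseline")
  f <- predict(relationship, samples, max_force = max_force,
               max_envelope = max_envelope)
  if (!is.null(baseline)) f[samples < baseline$rest_envelope_level] <- 0
  f
}

#' Upper-body weight fraction used by the vertical force balance
#'
#' The weight borne above L4/L5 is taken as 67% of total body weight.
#' @export
UPPER_BODY_WEIGHT_FRACTION <- 0.67

#' Compute the L4/L5 compressive load series
#'
#' Vertical force balance at the L4/L5 joint: the compressive load is the
#' vertical component of the upper-body weight plus the vertical components
#' of the muscle forces crossing the joint,
#' `F_J(t) = f_UBW * BW * cos(theta_UBW(t)) + sum_M F_M(t) * sin(theta_M)`,
#' with `f_UBW = 0.67` and `theta_M` each muscle's inclination from
#' [muscle_angles()]. Optionally the held ball's weight can be added to the
#' upper-body term for sensitivity analyses (off by default; the balance
#' lists only upper-body weight and muscle terms).
#'
#' @param forces Named list of per-channel force series (N, per side), names
#'   in [EMG_CHANNELS]; missing channels contribute zero.
#' @param geometry [muscle_angles()]-annotated geometry table.
#' @param subject A [subject_record()].
#' @param torso_angle Torso inclination series, degrees from vertical.
#' @param time Time vector, s.
#' @param include_ball_weight If `TRUE`, add `ball_mass * g * cos(theta)`.
#' @param ball_mass Ball mass, kg (used only when `include_ball_weight`).
#' @param carrying Logical series: `TRUE` while the ball is held (used only
#'   when `include_ball_weight`).
#' @return An object of class `load_series`: data.frame with `time`, `f_j`
#'   (N), `f_j_pct_bw` (% body weight) plus per-channel force columns;
#'   attribute `subject`.
#' @export
compute_load_series <- function(forces, geometry, subject, torso_angle, time,
                                include_ball_weight = FALSE, ball_mass = 8,
                                carrying = NULL) {
  stopifnot(inherits(subject, "emg_subject"))
  n <- length(torso_angle)
  if (length(time) != n) stop("time and torso_angle are misaligned")
  lens <- vapply(forces, length, integer(1))
  if (length(lens) && any(lens != n))
    stop("muscle force series are misaligned with the torso angle series")
  bw <- subject$body_weight
  fj <- UPPER_BODY_WEIGHT_FRACTION * bw * cospi(torso_angle / 180)
  if (include_ball_weight) {
    held <- if (is.null(carrying)) rep(TRUE, n) else carrying
    fj <- fj + ball_mass * GRAVITY * cospi(torso_angle / 180) * held
  }
  inc <- function(ch) {
    grp <- EMG_CHANNEL_GROUPS[[ch]]
    geometry$inclination[geometry$muscle == grp]
  }
  out <- data.frame(time = time)
  for (ch in EMG_CHANNELS) {
    f <- if (ch %in% names(forces)) forces[[ch]] else rep(0, n)
    fj <- fj + f * sinpi(inc(ch) / 180)
    out[[paste0("f_", tolower(ch))]] <- f
  }
  out$f_j <- fj
  out$f_j_pct_bw <- 100 * fj / bw
  attr(out, "subject") <- subject
  class(out) <- c("load_series", "data.frame")
  out
}

#' @export
print.load_series <- function(x, ...) {
  cat(sprintf(paste0("<load_series> %d samples over %.1f s: F_J ",
                     "[%.0f, %.0f] N (%.0f-%.0f %%BW)\n"),
              nrow(x), diff(range(x$time)), min(x$f_j), max(x$f_j),
              min(x$f_j_pct_bw), max(x$f_j_pct_bw)))
  invisible(x)
}

#' @export
plot.load_series <- function(x, normalized = TRUE, ...) {
  y <- if (normalized) x$f_j_pct_bw else x$f_j
  graphics::plot(x$time, y, type = "l", xlab = "time (s)",
                 ylab = if (normalized) "L4/L5 compression (% BW)"
                        else "L4/L5 compression (N)", ...)
  invisible(x)
}

#' Segment lift cycles from the ball-height channel
#'
#' A lift cycle starts when the ball first rises above the resting floor by
#' the lift threshold and ends when it returns to the floor band. The floor
#' is estimated as a low quantile of the height series; hysteresis (a lower
#' return threshold) prevents chatter at the boundary. Incomplete trailing
#' cycles are discarded. A flat series yields zero cycles, not an error.
#'
#' @param ball_height Ball height series, m.
#' @param time Time vector, s (optional; defaults to sample index).
#' @param lift_threshold Rise above the floor that starts a cycle, m.
#' @param hysteresis Return threshold is `lift_threshold - hysteresis`, m.
#' @param floor_quantile Quantile of the series used as the resting floor.
#' @return A data.frame of class `lift_cycles` with columns `start`, `end`
#'   (sample indices) and `start_time`, `end_time` (s).
#' @export
segment_lift_cycles <- function(ball_height, time = NULL,
                                lift_threshold = 0.02, hysteresis = 0.01,
                                floor_quantile = 0.05) {
  if (length(ball_height) == 0) stop("empty ball-height series")
  if (is.null(time)) time <- seq_along(ball_height)
  floor <- stats::quantile(ball_height, floor_quantile, names = FALSE)
  up <- floor + lift_threshold
  down <- floor + lift_threshold - hysteresis
  starts <- integer(0); ends <- integer(0)
  lifted <- FALSE; s <- NA_integer_
  for (i in seq_along(ball_height)) {
    if (!lifted && ball_height[i] > up) {
      lifted <- TRUE; s <- i
    } else if (lifted && ball_height[i] < down) {
      lifted <- FALSE
      starts <- c(starts, s); ends <- c(ends, i)
    }
  }
  res <- data.frame(start = starts, end = ends,
                    start_time = time[starts], end_time = time[ends])
  class(res) <- c("lift_cycles", "data.frame")
  res
}

#' Impulse of the compressive load over a lift cycle
#'
#' Trapezoidal integral of `F_J` from cycle start to cycle end, reported
#' both raw (N·s) and normalized by body weight (s).
#'
#' @param load A [compute_load_series()] result (or data.frame with `time`
#'   and `f_j`).
#' @param cycle One row of a [segment_lift_cycles()] result (or a list with
#'   `start` and `end` indices).
#' @param body_weight Body weight, N.
#' @return List with `impulse` (N·s) and `impulse_bw` (s).
#' @export
compute_impulse <- function(load, cycle, body_weight) {
  i0 <- cycle$start; i1 <- cycle$end
  if (length(i0) != 1 || length(i1) != 1 || i0 >= i1)
    stop("cycle must have start < end")
  if (i0 < 1 || i1 > nrow(load)) stop("cycle outside the load series")
  idx <- i0:i1
  tt <- load$time[idx]; ff <- load$f_j[idx]
  imp <- sum(diff(tt) * (ff[-1] + ff[-length(ff)]) / 2)
  list(impulse = imp, impulse_bw = imp / body_weight)
}

#' Per-subject impulse summary over all lift cycles
#'
#' Computes the impulse of every segmented cycle and summarises with the
#' per-subject mean and SD, raw and body-weight-normalized.
#'
#' @param load A [compute_load_series()] result.
#' @param cycles A [segment_lift_cycles()] result.
#' @param body_weight Body weight, N; defaults to the load series' subject.
#' @return An object of class `impulse_summary`: data.frame `per_cycle`
#'   (impulse, impulse_bw) plus `mean`, `sd`, `mean_bw`, `sd_bw`, `n_cycles`.
#' @export
summarize_impulse <- function(load, cycles, body_weight = NULL) {
  if (is.null(body_weight)) {
    subj <- attr(load, "subject")
    if (is.null(subj)) stop("supply body_weight: load series has no subject")
    body_weight <- subj$body_weight
  }
  per <- lapply(seq_len(nrow(cycles)), function(i)
    compute_impulse(load, cycles[i, ], body_weight))
  imp <- vapply(per, `[[`, numeric(1), "impulse")
  structure(list(per_cycle = data.frame(impulse = imp,
                                        impulse_bw = imp / body_weight),
                 mean = mean(imp), sd = stats::sd(imp),
                 mean_bw = mean(imp) / body_weight,
                 sd_bw = stats::sd(imp) / body_weight,
                 n_cycles = length(imp)),
            class = "impulse_summary")
}

#' @export
print.impulse_summary <- function(x, ...) {
  cat(sprintf(paste0("<impulse_summary> %d cycles: %.0f ± %.0f N·s ",
                     "(%.2f ± %.2f s normalized)\n"),
              x$n_cycles, x$mean, if (is.na(x$sd)) 0 else x$sd,
              x$mean_bw, if (is.na(x$sd_bw)) 0 else x$sd_bw))
  invisible(x)
}

#' Resample a load curve to percent-of-task
#'
#' Linearly resamples the compressive-load values of one cycle onto a
#' common 101-point 0-100% task grid so curves from different models,
#' subjects or cycle durations can be overlaid.
#'
#' @param values Load values over the cycle (any length >= 2).
#' @return Numeric vector of length 101.
#' @export
normalize_cycle_curve <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 samples to normalize a cycle")
  stats::approx(seq(0, 100, length.out = n), values,
                xout = seq(0, 100, by = 1))$y
}

#' Estimate the full load pipeline for one task trial
#'
#' Convenience wrapper: predicts the six muscle-force series from the
#' trial's envelopes with the chosen relationships, computes the L4/L5 load
#' series, segments lift cycles from the ball height and summarises the
#' impulse.
#'
#' @param trial A [task_trial()].
#' @param relationships Named list of [force_emg] fits (one per channel).
#' @param geometry [muscle_angles()]-annotated geometry.
#' @param baselines Named list of `rest_baseline` objects, or `NULL`.
#' @param maxima For general relationships: named list per channel with
#'   `max_force`, `max_envelope`.
#' @param ... Passed to [compute_load_series()].
#' @return List with `load` (load_series), `cycles`, `impulse`.
#' @export
estimate_task_load <- function(trial, relationships, geometry,
                               baselines = NULL, maxima = NULL, ...) {
  stopifnot(inherits(trial, "task_trial"))
  forces <- list()
  for (ch in EMG_CHANNELS) {
    rel <- relationships[[ch]]
    if (is.null(rel)) stop("no relationship supplied for channel ", ch)
    mx <- maxima[[ch]]
    forces[[ch]] <- predict_muscle_force(
      rel, trial$envelopes[, ch], baseline = baselines[[ch]],
      max_force = mx$max_force, max_envelope = mx$max_envelope)
  }
  load <- compute_load_series(forces, geometry, trial$subject,
                              trial$torso_angle, trial$time, ...)
  cycles <- segment_lift_cycles(trial$ball_height, trial$time)
  imp <- if (nrow(cycles) > 0) summarize_impulse(load, cycles) else NULL
  list(load = load, cycles = cycles, impulse = imp)
}
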