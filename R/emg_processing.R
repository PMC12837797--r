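#' Trunk sEMG channel labels
#'
#' The six surface-EMG channels the pipeline consumes: right/left erector
#' spinae (extensors), right/left rectus abdominis and right/left external
#' obliques (flexors).
#'
#' @format Character vector of length 6.
#' @export
EMG_CHANNELS <- c("RES", "LES", "RRA", "LRA", "REO", "LEO")

#' Muscle group of each EMG channel
#'
#' Maps each bilateral channel to its muscle group (ES, RA or EO). Bilateral
#' muscle forces are treated as equal, so both sides of a pair share one
#' calibrated geometry and one solved group force.
#'
#' @format Named character vector.
#' @export
EMG_CHANNEL_GROUPS <- c(RES = "ES", LES = "ES", RRA = "RA", LRA = "RA",
                        REO = "EO", LEO = "EO")

#' Construct a raw sEMG trace
#'
#' A single-channel raw surface-EMG recording with its sampling rate and the
#' kind of trial it came from.
#'
#' @param samples Numeric vector of raw signal values (arbitrary but
#'   consistent units). Must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel Channel label, one of [EMG_CHANNELS].
#' @param trial_kind One of `"rest"`, `"vct"`, `"task"`.
#' @return An object of class `emg_trace`.
#' @export
emg_trace <- function(samples, sampling_rate, channel,
                      trial_kind = c("rest", "vct", "task")) {
  trial_kind <- match.arg(trial_kind)
  channel <- match.arg(channel, EMG_CHANNELS)
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel = channel, trial_kind = trial_kind),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> channel %s (%s trial): %d samples @ %g Hz\n",
              x$channel, x$trial_kind, length(x$samples), x$sampling_rate))
  invisible(x)
}

#' Rest-trial baseline for one channel
#'
#' Characterises the supine rest recording of a channel by its DC offset (the
#' scalar mean of the raw rest trace) and its rest envelope level (the mean
#' RMS envelope of the offset-removed rest trace). Envelope samples below the
#' rest level are treated as zero muscle force downstream.
#'
#' @param rest_trace An [emg_trace()] from a rest trial.
#' @param window_width RMS window used for the rest envelope (odd, samples).
#' @return An object of class `rest_baseline` with fields `channel`,
#'   `dc_offset`, `rest_envelope_level`.
#' @export
compute_rest_baseline <- function(rest_trace, window_width = 51L) {
  stopifnot(inherits(rest_trace, "emg_trace"))
  if (length(rest_trace$samples) == 0) stop("rest trace is empty")
  dc <- mean(rest_trace$samples)
  centred <- emg_trace(rest_trace$samples - dc, rest_trace$sampling_rate,
                       rest_trace$channel, rest_trace$trial_kind)
  env <- rms_envelope(centred, window_width = window_width)
  structure(list(channel = rest_trace$channel, dc_offset = dc,
                 rest_envelope_level = mean(env$samples)),
            class = "rest_baseline")
}

#' @export
print.rest_baseline <- function(x, ...) {
  cat(sprintf("<rest_baseline> %s: dc_offset = %.4g, rest level = %.4g\n",
              x$channel, x$dc_offset, x$rest_envelope_level))
  invisible(x)
}

#' Remove the rest-trial DC offset from a trace
#'
#' Subtracts the scalar rest-trial mean from every sample. Rest and active
#' trials differ in length, so a scalar subtraction is the well-defined
#' reading of rest-referenced offset removal.
#'
#' @param trace An [emg_trace()].
#' @param baseline A [compute_rest_baseline()] result for the same channel.
#' @return An `emg_trace` with the offset removed.
#' @export
remove_dc_offset <- function(trace, baseline) {
  stopifnot(inherits(trace, "emg_trace"), inherits(baseline, "rest_baseline"))
  if (trace$channel != baseline$channel)
    stop(sprintf("channel mismatch: trace %s vs baseline %s",
                 trace$channel, baseline$channel))
  emg_trace(trace$samples - baseline$dc_offset, trace$sampling_rate,
            trace$channel, trace$trial_kind)
}

# Centered moving RMS with edge truncation, O(n) via cumulative sums.
moving_rms <- function(x, w) {
  n <- length(x)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x^2))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Moving RMS envelope of an sEMG trace
#'
#' Centered root-mean-square filter. The window is truncated at the edges
#' (no padding with phantom data), so output length equals input length and
#' every output sample is the RMS of real samples only.
#'
#' @param trace An [emg_trace()] (normally offset-removed first).
#' @param window_width Window width in samples; odd, >= 1. Default 51.
#' @return An object of class `emg_envelope` with non-negative `samples`,
#'   `sampling_rate`, `channel`, `window_width`.
#' @export
rms_envelope <- function(trace, window_width = 51L) {
  stopifnot(inherits(trace, "emg_trace"))
  window_width <- as.integer(window_width)
  if (window_width < 1L || window_width %% 2L == 0L)
    stop("window_width must be odd and >= 1")
  structure(list(samples = moving_rms(trace$samples, window_width),
                 sampling_rate = trace$sampling_rate,
                 channel = trace$channel, window_width = window_width),
            class = "emg_envelope")
}

#' Construct an envelope object directly
#'
#' Wraps already-enveloped samples (e.g. read from file, or synthesised at
#' the envelope level) in the container the calibration and load stages
#' consume.
#'
#' @param samples Non-negative numeric vector.
#' @param sampling_rate Hz (> 0).
#' @param channel Channel label.
#' @param window_width Window the envelope was produced with, if known.
#' @return An `emg_envelope`.
#' @export
emg_envelope <- function(samples, sampling_rate, channel, window_width = NA) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)) || any(samples < 0))
    stop("envelope samples must be finite and >= 0")
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  channel <- match.arg(channel, EMG_CHANNELS)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel = channel, window_width = window_width),
            class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %s: %d samples @ %g Hz (window %s)\n",
              x$channel, length(x$samples), x$sampling_rate,
              format(x$window_width)))
  invisible(x)
}

#' Flag sub-rest envelope samples as zero muscle force
#'
#' Envelope samples below the channel's rest envelope level carry no force
#' information: downstream force prediction maps them to zero. The envelope
#' values themselves are left unchanged; only the mask is added.
#'
#' @param envelope An `emg_envelope`.
#' @param baseline A `rest_baseline` for the same channel.
#' @return The envelope with a logical `zero_force_mask` field (`TRUE` where
#'   the sample is below the rest level).
#' @export
apply_rest_threshold <- function(envelope, baseline) {
  stopifnot(inherits(envelope, "emg_envelope"),
            inherits(baseline, "rest_baseline"))
  if (envelope$channel != baseline$channel)
    stop(sprintf("channel mismatch: envelope %s vs baseline %s",
                 envelope$channel, baseline$channel))
  envelope$zero_force_mask <- envelope$samples < baseline$rest_envelope_level
  envelope
}

#' Resample an envelope onto a new timebase
#'
#' Linear interpolation onto a uniform grid at `target_rate`, spanning the
#' same duration. Endpoints are preserved. Used to align EMG envelopes with
#' kinematic channels recorded at a different rate.
#'
#' @param envelope An `emg_envelope`.
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return An `emg_envelope` at `target_rate`.
#' @export
resample_to <- function(envelope, target_rate) {
  stopifnot(inherits(envelope, "emg_envelope"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be > 0")
  n <- length(envelope$samples)
  if (n == 1L || target_rate == envelope$sampling_rate) {
    envelope$sampling_rate <- target_rate
    return(envelope)
  }
  t_src <- (seq_len(n) - 1) / envelope$sampling_rate
  dur <- t_src[n]
  t_new <- seq(0, dur, by = 1 / target_rate)
  y <- stats::approx(t_src, envelope$samples, xout = t_new, rule = 2)$y
  emg_envelope(y, target_rate, envelope$channel, envelope$window_width)
}
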