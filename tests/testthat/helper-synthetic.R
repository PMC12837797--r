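# Small, fast synthetic configurations used across test files. The envelope
# timebase is reduced from the 2000 Hz default: envelopes are slow signals,
# so a coarser grid changes sample counts, not the round-trip identities.
fast_config <- function(seed = 1, noise_sd = 0, emg_sampling_rate = 100,
                        ...) {
  synthetic_config(seed = seed, noise_sd = noise_sd,
                   emg_sampling_rate = emg_sampling_rate, ...)
}

# Full noise-free calibration for one synthetic subject at one speed.
calibrate_synthetic <- function(synth, config, speed = 60,
                                baselines = NULL) {
  vcts <- lapply(seq_along(config$effort_levels), function(k)
    generate_vct(synth, config, speed, config$effort_levels[k],
                 trial_id = k))
  curve <- fit_gravity_calibration(vcts[[1]]$rest_sweep$angle,
                                   vcts[[1]]$rest_sweep$torque)
  calibrate_relationships(vcts, curve, synth$truth$geometry,
                          baselines = baselines)
}

# The relationship form each muscle group truly follows in the generator.
true_form <- function(synth, channel) {
  synth$truth$relationships[[EMG_CHANNEL_GROUPS[[channel]]]]$form
}

# Relationships matching the ground-truth forms, taken from a calibration.
fitted_true_relationships <- function(cal, synth, speed = 60) {
  out <- lapply(EMG_CHANNELS, function(ch)
    cal$fits[[as.character(speed)]][[true_form(synth, ch)]][[ch]])
  stats::setNames(out, EMG_CHANNELS)
}
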