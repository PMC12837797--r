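---
title: "Estimating L4/L5 compressive loading from calibrated trunk sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating L4/L5 compressive loading from calibrated trunk sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbarload)
```

## The problem

Compressive loading of the lumbar spine — in particular at the L4/L5 motion
segment, the most frequently impaired level — cannot be measured directly in
healthy people. Surface electromyography (sEMG) offers a noninvasive proxy:
if the mapping from a muscle's electrical activity to its force is known,
the forces of the trunk muscles crossing L4/L5 can be estimated during any
dynamic task, and the joint's axial compression follows from a force
balance. The catch is that the force-to-sEMG mapping varies strongly
between people (electrode placement, muscle size, fibre composition), so a
single population gain is a blunt instrument. `lumbarload` implements a
subject-specific alternative: each person's mapping is calibrated from
isokinetic dynamometer trials, then applied to lifting-task recordings.

Six channels are used throughout: right and left erector spinae (`RES`,
`LES`, the trunk extensors) and the flexors rectus abdominis (`RRA`, `LRA`)
and external obliques (`REO`, `LEO`). All trials are sagittal-plane, so
bilateral forces are treated as equal.

## Signal processing

Raw sEMG is referenced to a 5 s supine rest recording: the scalar mean of
the rest trace is subtracted as the channel's DC offset, and a centred
moving-RMS filter with a 51-sample window produces the envelope
(`rms_envelope()`). The window is in samples because the acquisition rate
of the envelope pipeline is configurable; edges truncate the window rather
than padding, so no sample is invented. Envelope values below the channel's
rest envelope level (the mean envelope of the offset-removed rest trace)
are treated as zero muscle force downstream — rest-level activity carries
no force information. The zero-force comparison is strict (`envelope <
rest level`), so a rest level of exactly zero masks nothing.

## Calibrating the force-to-sEMG relationship

During a voluntary-contraction trial (VCT) the subject flexes and extends
the trunk against an isokinetic dynamometer through three concentric cycles
at a fixed angular speed (30 or 60 deg/s), at maximum and sub-maximal
effort. The measured torque contains an angle-dependent artifact from the
torso's own weight resting on the lever. That artifact is *measured*, not
modelled: a rest sweep with the subject relaxed gives torque versus lever
angle, fitted as a piecewise-linear calibration curve
(`fit_gravity_calibration()`). A weight-times-sine model is deliberately
not assumed — the torso weight actually borne by the dynamometer does not
follow it. After subtraction, the corrected moment is divided by the
lever-arm length `d_L` and treated as the equivalent resistive force at the
pad, `M_B*` (N); this convention makes the moment balances below
dimensionally consistent as printed.

Samples are labelled flexion or extension by the sign of the lever angular
velocity, with a ±2 deg/s deadband around direction reversals excluded.
The moment balances are:

* extension — the whole corrected moment is attributed to the erector
  spinae: `M_B* · d_L = F_ES · d_ES · cos(θ_ES)`;
* flexion — shared by rectus abdominis and external obliques:
  `M_B* · d_L = F_RA · d_RA · cos(θ_RA) + F_EO · d_EO · cos(45°)`, closed
  with the equal-stress assumption `F_EO = r · F_RA`, `r` the EO:RA
  cross-sectional-area ratio.

Muscle geometry (CSA, moment arm) comes from a linear anthropometric
coefficient table applied to the measured torso depth and width
(`estimate_muscle_geometry()`). The shipped defaults land in physiological
ranges (ES CSA ≈ 20 cm², moment arm ≈ 5.4 cm; RA moment arm ≈ 9 cm) and
are meant to be replaced with literature regression values via the
editable plain-text table (`read_coefficient_table()`); every validation
in this package is relative to whichever table is in use, because the
synthetic ground truth uses the same table.

Each muscle's inclination is a single angle used in both balances: its
cosine scales moment effectiveness and its sine scales the vertical
(compressive) component. The ES and RA angles are constructed as
`asin(d_M / d_L)`; the EO crossing angle is fixed at 45°. Two ambiguities
are acknowledged here rather than hidden. First, the abdominal crossing
angle can be read either as fixed at 45° or as estimated from geometry; the
default estimates it, and `muscle_angles(ra_angle_fixed_45 = TRUE)` flips
the reading. Second, using the *same* angle in the moment balance (cosine)
and the vertical balance (sine) is one self-consistent interpretation of
the model's printed equations; the construction is isolated in
`muscle_angles()` so it can be swapped without touching the solvers.

Solved forces are halved across sides and paired with each side's own
envelope (`pair_force_emg()`), pooled over the three trials at a speed, and
fitted by ordinary least squares in two candidate forms
(`fit_force_emg()`):

* linear: `F = a + b·s`
* logarithmic: `F = a + b·ln(s)`

Predictions clamp at zero. A *general* relationship pools all subjects
after scaling each subject's samples to [0, 1] by that subject's maximum
force and envelope (`build_general_relationship()`); predictions for a new
subject rescale by that subject's own maxima. Goodness is scored as percent
error: `100 · mean(|F_pred − F_obs|) / max(F_obs)`. Normalising by the
maximum rather than the per-sample observation is a deliberate choice —
observed force passes through zero during every cycle and a per-sample
ratio would blow up there. The form with the lower percent error is
selected per muscle, ties breaking toward the simpler linear form.

## Estimating the task load

For a stoop-to-stand lifting trial, each channel's envelope is pushed
through its calibrated relationship (60 deg/s fits by default, matching the
task's contraction speeds), sub-rest samples are zeroed, and the L4/L5
compression follows from the vertical force balance:

`F_J(t) = 0.67 · BW · cos(θ_UBW(t)) + Σ_M F_M(t) · sin(θ_M)`

where the upper body carries 67% of body weight `BW` and `θ_UBW` is the
torso's inclination from vertical (from the sacrum→sternum marker vector).
The held ball's weight is not part of the balance; a sensitivity switch
(`include_ball_weight`) can add it.

Lift cycles are segmented from the ball-marker height: a cycle starts when
the ball rises 2 cm above the resting floor (the 5th percentile of the
height series) and ends when it returns within 1 cm of the floor
(hysteresis prevents chatter); incomplete trailing excursions are dropped.
Both thresholds are configurable — the verbal definition of a lift fixes
neither. Impulse is the trapezoidal integral of `F_J` over a cycle,
reported raw (N·s) and normalised by body weight (s); both are kept because
normalised loading curves are the natural cross-subject comparison while
raw N·s values match how such impulses are usually quoted. For overlaying
curves across models and cycle durations, each cycle is resampled to a
101-point 0–100 %-of-task grid (`normalize_cycle_curve()`,
`compare_load_curves()`), which also makes the curves invariant to the
recording rate. Externally produced load curves (e.g. from a rigid-body
inverse-dynamics model, or in vivo recordings) enter the comparison as
plain delimited text; `paired_t_test()` and `normality_check()` compare
per-subject mean impulses between models, and `build_factor_grid()`
assembles the muscle × specificity × linearity × speed percent-error grid,
exported long-form for any standard ANOVA machinery.

## The synthetic study

No public recordings accompany this kind of protocol, so the package ships
a generator (`synthetic_config()`, `generate_subject()`, `generate_vct()`,
`generate_slss_trial()`) that emulates the study conditions: a cohort with
BMI ~ N(25.2, 0.8²) truncated to non-obese range, 5 s rest traces,
three-cycle VCTs at 30 and 60 deg/s with per-trial efforts {1.0, 0.7, 0.4},
and 30 s stoop-to-stand bouts with an 8 kg ball and 2 s upright holds.
Defaults the protocol leaves open were fixed once at realistic values:
envelope rate 2000 Hz, kinematics 100 Hz, envelope noise SD 0.02 on a
unit-maximum scale, lever-arm length 0.30 × stature, torso flexed to 75°
when stooped.

Every subject carries a known ground truth: linear ES and logarithmic
RA/EO relationships with per-subject gain (uniform on [1, 2.5]) and shape
variation, geometry derived from the same coefficient table the pipeline
uses, and a cubic-in-angle gravity-artifact curve. Trials are built
*forward* through the same moment and force balances the pipeline inverts:
activations drive envelopes, envelopes drive true forces, forces drive
torque. Three consequences matter for testing:

* with `noise_sd = 0`, calibration recovers the true coefficients and the
  task pipeline reproduces the stored true load series to machine
  precision (observed ~1e−15, asserted < 1e−6) — the rest sweep shares the
  triangle wave's exact angle grid, so the piecewise-linear calibration is
  evaluated only at its own nodes and introduces no interpolation error;
* the EO force is prescribed as exactly `r · F_RA`, so the flexion solver's
  equal-stress split is consistent with the data it sees;
* generation is deterministic per (config, subject id, trial id): sub-seeds
  are derived arithmetically, so trials can be regenerated in any order.

What the generator does **not** emulate: raw-EMG spectral content (signals
are synthesised at the envelope level, since the pipeline only consumes
envelopes), motor-unit physiology, antagonist co-activation, marker clouds
beyond the channels consumed, and force–length/velocity dynamics. Passing
round-trip tests therefore demonstrates that the *estimator* is exact and
unbiased given the model's assumptions — not that the assumptions hold in
real recordings.

## Validation problem sizes and statistical behaviour

The test suite and the acceptance script run the generator at a 100 Hz
envelope timebase (50 Hz for the noisy replicate study) rather than the
2000 Hz default: envelopes are slow signals, so the coarser grid changes
sample counts, not any round-trip identity. Population checks use 20
subjects × 100 seeded populations; on every such population the specific
relationships outperform the general ones for all six muscles, as the
gain/shape heterogeneity built into the cohort predicts.

One statistical property deserves emphasis. Under envelope noise, ordinary
least squares of solved force on the *measured* envelope is an
errors-in-variables regression: the slope is attenuated by the factor
`var(s) / (var(s) + σ²)`, a bias that does not shrink with more samples,
while the reported standard errors do. With noise at 5% of the maximum
envelope, the attenuation of the ES linear slope is about −2.3%, which
sits near three standard errors at a few hundred samples per fit and many
standard errors at the full acquisition rate. The rest-threshold exclusion
removes the worst-affected low-envelope samples and largely protects the
logarithmic fits, but the residual ES-slope attenuation is a property of
the estimator the model prescribes, not of this implementation — the
noise-free recovery at ~1e−15 pins the implementation itself. Users who
need unattenuated coefficients under heavy envelope noise should treat the
fitted slopes as lower bounds or apply an errors-in-variables correction
downstream.

Other numerical choices: the paired t-test and Shapiro–Wilk check wrap the
standard routines (`stats::t.test`, `stats::shapiro.test`) and the t-test's
type-I error is verified by simulation to sit in [0.04, 0.06] at α = 0.05;
integration is trapezoidal (exact for the constant and piecewise-linear
loads used as closed-form checks); interpolation is linear with endpoint
clamping for the gravity curve and endpoint preservation for resampling.

## Known limitations

Only six muscles carry the whole moment; co-activation is not modelled, so
loads are underestimated when antagonists fire and extensor-dominant
subjects will look abnormally loaded. Geometry comes from anthropometric
regressions, not imaging. The percent-error definition, the lift-threshold
constants, and the arcsin angle construction are documented defaults, each
isolated behind a single function or argument so they can be replaced
without touching the rest of the pipeline.
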