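# lumbarload

Subject-specific estimation of L4/L5 compressive loading from trunk
surface EMG during dynamic lifting.

## What it does, and for whom

Axial compression of the L4/L5 motion segment — the lumbar level most
often implicated in low back pain — cannot be measured directly in healthy
people. This package implements an EMG-driven estimate for biomechanics
and rehabilitation researchers: each subject's muscle force-to-sEMG
relationships are **calibrated** from isokinetic voluntary-contraction
trials (VCTs) via sagittal moment balances, then **applied** to
lifting-task recordings through a vertical force balance, yielding a
compressive load curve and per-lift impulse summaries.

Six channels are modelled: right/left erector spinae (extensors) and
right/left rectus abdominis and external obliques (flexors).

The core relations, in the package's notation:

* extension moment balance: `M_B* · d_L = F_ES · d_ES · cos θ_ES`
* flexion moment balance:
  `M_B* · d_L = F_RA · d_RA · cos θ_RA + F_EO · d_EO · cos 45°`,
  closed by the cross-sectional-area ratio split `F_EO = r · F_RA`
* force-to-sEMG forms: `F = a + b·s` (linear) and `F = a + b·ln s`
  (logarithmic), fitted per muscle, per speed, as subject-specific or
  pooled-normalised ("general") relationships
* vertical force balance during the task:
  `F_J = 0.67·BW·cos θ_UBW + Σ_M F_M · sin θ_M`
* impulse per lift cycle: `∫ F_J dt` (trapezoidal), raw and normalised by
  body weight

`M_B*` is the dynamometer moment corrected for the torso-weight artifact
by a measured rest-sweep calibration curve, expressed as force at the
lever pad. Because no public recordings exist for this protocol, the
package includes a synthetic motion-lab generator with known ground truth
(subjects, rest trials, VCTs, stoop-to-stand trials), which makes the
whole pipeline testable by parameter recovery.

## Worked example

Calibrate one synthetic subject and estimate the load of a 30 s
stoop-to-stand bout (three lifts of an 8 kg ball):

```r
library(lumbarload)

cfg <- synthetic_config(seed = 42, n_subjects = 8, emg_sampling_rate = 100)
sy  <- generate_subject(cfg, 1)
sy$subject
#> <subject S01> mass 80.5 kg (BW 790 N), height 1.77 m, torso 0.198 x 0.309 m, leg 0.92 m

## calibration: three VCTs at 60 deg/s, gravity-corrected via the rest sweep
vcts  <- lapply(1:3, function(k)
  generate_vct(sy, cfg, 60, cfg$effort_levels[k], trial_id = k))
curve <- fit_gravity_calibration(vcts[[1]]$rest_sweep$angle,
                                 vcts[[1]]$rest_sweep$torque)
baselines <- lapply(generate_rest_trial(sy, cfg), compute_rest_baseline)
cal <- calibrate_relationships(vcts, curve, sy$truth$geometry,
                               baselines = baselines)

summary(cal$fits[["60"]][["linear"]][["RES"]])
#> <force_emg> specific linear fit [RES] @ 60 deg/s: F = a + b*s, a = 211.2, b = 2175 (n = 1314)
#>   se(a) = 2.425, se(b) = 4.556, residual sd = 44.81, RSS = 2.63493e+06
#>   force range [226.1, 2393] N, envelope range [0.0202, 1.029]
```

The right erector spinae fit says: each unit of envelope maps to ~2175 N
of per-side extensor force, calibrated from 1314 extension-phase samples.
Score both candidate forms and keep the lower-error one:

```r
err <- sapply(c(linear = "linear", logarithmic = "logarithmic"), function(f)
  percent_error(cal$fits[["60"]][[f]][["RES"]],
                cal$samples[cal$samples$muscle == "RES", ]))
round(err, 2)
#>      linear logarithmic
#>        1.49        7.89
select_best_relationship(err)
#> [1] "linear"
```

Apply the calibration to the lifting task:

```r
slss <- generate_slss_trial(sy, cfg)
rels <- lapply(EMG_CHANNELS, function(ch)
  cal$fits[["60"]][[sy$truth$relationships[[EMG_CHANNEL_GROUPS[[ch]]]]$form]][[ch]])
names(rels) <- EMG_CHANNELS
res <- estimate_task_load(slss, rels, sy$truth$geometry, baselines = baselines)
res$load
#> <load_series> 3001 samples over 30.0 s: F_J [1024, 1708] N (130-216 %BW)
res$impulse
#> <impulse_summary> 3 cycles: 7335 ± 7 N·s (9.29 ± 0.01 s normalized)
```

The load curve peaks a little over twice body weight mid-lift and bottoms
out while standing (the 67% upper-body weight term plus residual muscle
tone); the three detected lift cycles integrate to about 7.3 kN·s of
compression each, i.e. 9.3 s of body weight per lift. `plot(res$load)`
draws the curve; `compare_load_curves()` overlays percent-of-task
normalised curves from other models for side-by-side comparison.

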