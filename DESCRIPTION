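Package: lumbarload
Title: Subject-Specific EMG-Driven Estimation of L4/L5 Compressive Loading
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates subject-specific muscle force-to-surface-EMG
    relationships for the trunk muscles (erector spinae, rectus abdominis,
    external obliques) from isokinetic voluntary-contraction trials via
    sagittal moment balances, then applies them through a vertical force
    balance to estimate L4/L5 compressive loading during dynamic lifting
    tasks. Includes rest-referenced RMS envelope processing, dynamometer
    gravity-artifact correction, linear and logarithmic relationship forms
    with specific (per-subject) and general (normalised, pooled) variants,
    lift-cycle segmentation with body-weight-normalised impulse integration,
    percent-error factor grids, and a synthetic motion-lab data generator
    with known ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
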