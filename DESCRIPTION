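Package: cadgait
Title: Cadence-Controlled Gait Analysis from Wearable Accelerometer Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cadence-controlled walking from foot-worn
    triaxial accelerometers. Provides a synthetic two-foot gait-signal
    simulator with exact ground-truth event annotations, zero-phase
    Butterworth preprocessing with leading-clearance time synchronisation,
    gait-cycle segmentation from the longitudinal axis (valley/zero-crossing/
    peak landmark detection with the 60 percent stance rule), extraction of
    the seven normalised gait periods, cadence-characteristic Pearson
    correlation tables with low/moderate/high banding, lateral-sway
    summaries, and an end-to-end reproducible pipeline that emits phase and
    period tables together with consistency validation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
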