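Package: gaitwave
Title: Step Detection and Real-World Gait-Speed Estimation from Waist-Worn Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects steps and estimates real-world gait speed from waist-worn
    tri-axial accelerometer recordings, with a focus on slow (orthogeriatric)
    walkers. Implements the 'stepwave' detector (short-time Fourier cadence
    estimation, plausibility gating, narrowband analytic-signal features via the
    Hilbert transform, phase-cycle step segmentation) and a per-step linear
    gait-speed model on the amplitude envelopes and their interactions, plus a
    legacy adaptive-threshold heel-strike detector ('stepslc') as comparator, a
    measuring-wheel (perambulator) reference-speed method, agreement statistics
    (Bland-Altman, regression agreement, RMSE, speed-binned differences), and a
    parameterized synthetic-gait simulator with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
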