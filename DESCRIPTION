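Package: falldetect
Title: Two-Stage Smartphone Fall Detection from Inertial Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An online fall-detection pipeline for smartphone inertial sensor
    data: irregularly sampled tri-axial accelerometer and gyroscope streams are
    segmented into 5-second windows, quality-gated, resampled to a 50 Hz grid,
    and summarised by 40 time-domain features. A two-stage detector - a 2 g
    peak-acceleration screen followed by an elastic-net regularized logistic
    regression with a percentile-calibrated alert threshold - classifies each
    window, emits portal-style event records with contextual metadata, and is
    evaluated with deployment metrics (sensitivity, precision, F1, false-alarm
    interval). A seeded synthetic IMU generator provides labeled ambulation,
    fall, stumble and phone-drop recordings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
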