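Package: camvitals
Title: Contactless Respiratory and Heart Rate Estimation from Near-Infrared Sleep Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Motion-based estimation of respiratory rate and heart rate from
    monochrome near-infrared video of a sleeping person. Tracks grid-selected
    feature points with pyramidal Lucas-Kanade optical flow, filters them by
    frame-to-frame displacement percentiles, and estimates rates on sliding
    30-second windows: principal component analysis for breathing, independent
    component analysis with harmonic-periodicity candidate scoring for heart
    rate. Includes gold-standard extractors (ECG R-peak detection with
    parabolic refinement, RIP dominant-frequency analysis), movement detection
    and exclusion logic, agreement metrics against the gold standard, a
    mean-hold baseline, and a synthetic-scene generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
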