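Package: gsrstress
Title: Galvanic Skin Response Stress Quantification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for galvanic skin response (GSR /
    electrodermal activity) streams from wearable sensors: 12-bit to
    10-bit ADC mapping, scalar Kalman filtering for noise reduction,
    per-subject baseline-calibrated dynamic range normalization onto a
    0-500 scale, four-band stress classification, and the Grove GSR
    voltage-divider skin-resistance calibration curve. Includes a
    seedable synthetic GSR stream and cohort simulator with ground-truth
    stress labels, a bundled printed cohort table fixture, a CSV/JSONL
    replay engine with per-stage timing instrumentation, and a command
    line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
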