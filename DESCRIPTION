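Package: physioval
Title: Three-Level Validity Assessment of Wearable Physiological Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A standardized protocol for assessing the validity of wearable
    electrodermal-activity (EDA) and cardiovascular (ECG/PPG) sensors against
    a laboratory reference device. Paired, time-synchronized recordings are
    compared on three levels: the signal level (lagged cross-correlation of
    the conditioned EDA signals), the parameter level (Bland-Altman agreement
    of SCL, SCR rate, SCR total amplitude, heart rate, SD and RMSSD of beat
    intervals against a-priori physiological boundaries), and the event level
    (stressor-effect detection with standard-error bars, reference-effect
    boundaries and habituation-decay fitting). Includes trough-to-peak SCR
    detection, beat detection with interval filtering and signal-quality
    gating, a seeded synthetic-cohort generator emulating a sing-a-song
    stress test and a noise-habituation task, and a reasoned per-level
    validity verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
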