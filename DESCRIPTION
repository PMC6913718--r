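Package: pcea
Title: Personal-Baseline Heart-Rate Arousal Classification Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-testable engine for ambulatory heart-rate biofeedback.
    Calibrates a personal resting heart-rate baseline (mean and standard
    deviation) from wrist photoplethysmography sensor events, classifies
    streaming heart rate into ten signed arousal levels (-5..-1, 1..5) as a
    physiological correlate of emotional arousal, gates user notifications by
    accelerometer-derived physical activity, and maintains an annotated event
    timeline with notes and a diary. Includes a seedable synthetic wrist-PPG
    and accelerometer stream simulator with known ground truth, so every
    stage can be exercised without hardware, plus batch command-line entry
    points for calibration, replay, and dashboard reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
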