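Package: emgkin
Title: Multi-Channel EMG to Swimming Kinematics Mapping and Sensorimotor
    Delay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synchronized multi-channel electromyography
    (EMG) and midline pose recordings from undulatory swimmers. Conditions
    raw EMG (mean adjustment, 50 Hz notch, 20-450 Hz bandpass, zero-phase),
    extracts activation envelopes and an 18-feature-per-channel input matrix,
    reduces tracked midline poses to four joint angles and reconstructs body
    pose by planar forward kinematics, trains dense, recurrent and
    convolutional regressors mapping EMG to joint angles, and computes the
    signed delay between EMG onset peaks and lateral-displacement extrema
    whose sign distribution separates muscle-driven from flow-driven body
    motion. Includes a synthetic trial generator with known per-channel
    lead/lag so every stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
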