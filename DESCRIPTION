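Package: attnephys
Title: Analysis of Attention-Task Electrophysiology, Photometry and Behavior in an Absence-Epilepsy Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for linking prefrontal interneuron activity and
    cortical oscillations to attention performance in an absence-epilepsy mouse
    model. Provides Morlet continuous-wavelet spectrograms and band power,
    adaptive spike-and-wave discharge (SWD) detection with duration and
    peak-frequency rules, dual-wavelength fiber-photometry motion correction and
    dF/F trial features, laminar current-source-density maps, intracellular
    IPSP-failure and spike-reduction metrics, operant attention-task scoring
    (accuracy by cue length, omissions, reaction times, repetitive responding),
    and cross-validated boosted-tree decoding of trial outcome with
    SMOTE/Tomek class rebalancing and a shuffled-label null. A synthetic-data
    module generates every input class with known ground truth so the full
    stack can be exercised and validated without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    e1071,
    xgboost,
    pROC,
    withr,
    generics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
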