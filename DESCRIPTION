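Package: pvrdx
Title: Forefoot Pulse Volume Recordings for Peripheral Arterial Disease Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of forefoot pulse volume recordings (PVR)
    for noninvasive detection of peripheral arterial disease in diabetic foot
    syndrome. Generates annotated synthetic PVR waveforms of the four classical
    morphology classes, detects fiducial points (waveform foot, systolic peak,
    dicrotic notch) and extracts the quantitative features upstroke time (UST),
    upstroke ratio (USR) and maximum systolic amplitude (MSA), grades curve
    morphology with a rule cascade, simulates limb-level cohorts calibrated to
    published feature distributions by GLASS stage and inframalleolar outflow,
    and evaluates diagnostic test accuracy (ROC with bootstrap confidence
    intervals, Youden cut-offs, 2x2 contingency metrics, Cohen's kappa,
    nonparametric group tests, revascularization response).
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
    pROC,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
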