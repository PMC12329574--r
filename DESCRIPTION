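Package: vocattn
Title: Noise-Vocoded Speech Under Divided Attention: Simulation and
    Multivariate Classification Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying degraded-speech perception under divided
    attention. Implements a Greenwood-spaced noise vocoder (cochlear-implant
    style channel vocoding with half-wave rectification envelope extraction),
    synthetic generators for a 2x2 dual-task design (behavioral trial tables
    and parcel-level brain-response matrices with planted condition effects),
    parcel-mean feature reduction of volumetric statistic maps, an exhaustive
    grid-searched gradient-boosted classification pipeline with stratified
    cross-validation, Shapley-value feature ranking with patience-based
    iterative selection, exact binomial chance-level calibration for
    classifier accuracy, pairwise binary models with direction-of-effect
    summaries, and signal-detection (d-prime) and correlation analytics for
    the behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    glmnet
Config/testthat/edition: 3
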