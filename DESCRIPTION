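Package: fearmvpa
Title: Multivoxel Pattern Analysis of Discriminative Fear Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for trial-wise decoding of
    conditioned-threat representations from voxel patterns. Generates
    balanced fear-conditioning experimental designs (CS+/CS- pairs in a
    reinforcement context, matched neutral pairs in a nonreinforcement
    context, crossed with stimulus complexity), simulates trial-wise voxel
    patterns or full BOLD time series, estimates single-trial response
    amplitudes with a beta-series GLM, and decodes stimulus identity with
    linear support-vector classifiers under running-index threefold
    cross-validation. Chance levels are calibrated by label permutation,
    accounting for the class imbalance that reinforced-trial exclusion
    creates; neutral-pair decoding is matched by trial subsampling.
    Includes cross-decoding across stimulus complexity, searchlight
    mapping of excess accuracy, and balanced within-subject factorial
    inference on accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    RNifti,
    stats,
    utils
Suggests:
    lme4,
    lmerTest,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
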