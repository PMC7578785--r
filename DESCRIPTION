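Package: svide
Title: Joint Coding of Subjective Value and Decision Entropy in Model-Based fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how subjective value (SV) and
    inverse decision entropy (iDE) are jointly encoded in BOLD signal during a
    mixed-gambles task. Fits a logistic choice model per participant to derive
    trial-wise SV, acceptance probability, and decision entropy; builds
    voxelwise general linear models with SV and iDE as mean-centred parametric
    modulators (double-gamma HRF, temporal derivatives, motion confounds,
    cosine high-pass, AR(1) prewhitening); pools runs with fixed effects and
    performs group-level random-effects inference with sign-flip permutation
    cluster correction, minimum-statistic conjunctions, and paired permutation
    contrasts. Joint-coding statistics include the 2x2 sign contingency with
    chi-squared test, ROI overlap percentages, voxelwise map correlations,
    z-scored gradient summation maps, and the loss-aversion voxel ratio. A
    synthetic data module generates gamble schedules, simulated choices, and
    4D BOLD volumes with known ground-truth encoding maps so that every stage
    can be validated against a known answer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
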