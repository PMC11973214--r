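Package: dbmaging
Title: Deformation-Based Morphometry of Normal Aging and Disease-Specific
    Brain Atrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes a subject-to-template stationary velocity field
    (SVF) into a normal-aging component (aging score, AS) and a
    disease-specific residual (AD-specific score, ADS) by voxel-wise
    orthogonal projection onto a one-year normal-aging field derived from
    an age-gapped template pair. Includes scaling-and-squaring SVF
    integration, image warping, a classical multiresolution SVF
    registration, the entropy focus criterion (EFC) sharpness metric,
    quantile-based outlier rejection on the aging-field magnitude,
    regional aggregation over segmentation-derived masks, cohort
    statistics (age-trend fits, ANCOVA age adjustment, pairwise t-tests
    with Bonferroni correction, Cohen's d), and a synthetic phantom and
    cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
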