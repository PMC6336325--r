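Package: petflow
Title: Relative Cerebral Blood Flow Surrogates from Dynamic Amyloid PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic and early-frame analysis of dynamic PIB PET as a
    surrogate for FDG glucose metabolism. Implements basis-function fitting
    of the simplified reference tissue model (SRTM) and its two-step variant
    (SRTM2) to produce voxelwise R1 (relative tracer delivery) parametric
    maps, time-weighted early-frame (ePIB) images, SUVR maps normalized to
    cerebellar grey matter, geometric transfer matrix partial-volume
    correction of regional means, and the agreement and group-difference
    statistics used to compare the measures: pooled regional regressions,
    Bland-Altman limits of agreement, per-region t-tests with
    Benjamini-Hochberg correction, and a permutation-based voxelwise
    cluster test. A synthetic-cohort generator with known regional ground
    truth (phantom atlas, Feng-style arterial input, one-tissue reference
    kinetics, flow-metabolism coupling) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
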