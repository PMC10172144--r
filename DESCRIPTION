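Package: somatomap
Type: Package
Title: Connectivity, Lag and Somatotopy Analysis of Interdigitated Motor Cortex
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for detecting inter-effector (somato-cognitive action
    network) organization in precentral gyrus functional data: seed-sweep
    Fisher-z functional connectivity, conservative connectivity contrasts,
    infra-slow time-delay (lag) matrices estimated by lagged cross-covariance
    with parabolic interpolation, block and event-related task GLM activation
    mapping, winner-take-all somatotopy, movement selectivity and coactivation
    profiles, and one- versus two-peak Gaussian activation-profile model
    comparison by nested F-test. Includes a synthetic cortical-strip BOLD
    generator with known ground truth (network memberships, pairwise lags,
    spatial activation peaks) so every stage can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
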