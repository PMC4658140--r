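Package: erptfce
Title: Mass-Univariate ERP Statistics with TFCE and Max-Statistic Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference machinery for event-related potential (ERP)
    studies with a between-subject group factor and within-subject condition
    factors. Provides a synthetic-data generator (scalp-like sensor layouts,
    spatially and temporally correlated ERP noise with injectable effects,
    continuous EEG with injectable artifacts, and an adaptive incentive-delay
    task simulator), a deterministic preprocessing chain (band-pass and notch
    filtering, downsampling, spherical-spline channel interpolation, average
    reference, threshold-based artifact rejection, epoching, condition
    averaging), mass-univariate mixed-design ANOVA F-maps over channel-time
    points, threshold-free cluster enhancement (TFCE) over a sensor adjacency
    graph, two-step max-statistic permutation inference with familywise error
    control, and region-of-interest repeated-measures ANCOVA with
    group-orthogonalized covariates and planned contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
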