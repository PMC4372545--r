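Package: delaymem
Title: Subsequent-Memory Analysis of Persistent Delay-Period fMRI Activity
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, fully synthetic-data-driven pipeline for high-resolution
    fMRI subsequent-memory analysis of delayed match-to-sample working memory
    tasks. Simulates complete participants (trial schedules, confidence-rated
    recognition behavior, 4D BOLD volumes with ground-truth encoding effects),
    builds first-level design matrices for three competing encoding models
    (sample-only, sample-plus-delay boxcar, and inverse-square decay of
    persistent activity), fits voxel-wise least-squares models, relates
    encoding coefficients to a linear memory-strength code with a weighted
    least-squares group model, performs max-statistic permutation family-wise
    error inference, and checks model fit with posterior predictive simulation
    of trial-locked region-of-interest time courses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
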