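Package: dynfn
Title: Dynamic Functional Networks from Motor Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds weighted, directed functional networks from pairwise
    spike-time statistics (confluent mutual information) of simultaneously
    recorded single units, tracks them through time in 200-ms sliding
    windows, and quantifies their behavioral specificity during an
    instructed-delay center-out reach task. Provides graph alignment
    scores grouped by reach-target separation, rate-matched inhomogeneous
    Poisson surrogate networks, weighted reciprocity with surrogate
    normalization, multilayer-perceptron decoding of reach direction from
    firing-rate and network features, window-wise significance timelines,
    low-dimensional embedding of network vectors, and a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
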