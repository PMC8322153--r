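Package: statewarp
Title: State-Dependent Warping of First-Spike Latency Noise Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pairwise first-spike latency
    stimulus-response distributions from repeated sensory stimulation.
    Extracts isolated clusters from two-dimensional latency point clouds
    with a two-stage density-based algorithm, estimates noise-correlation
    angles of their first principal component by bootstrap with empirical
    confidence intervals, controls for stimulus-response adaptation via
    stationarity criteria, first-order differencing and automated
    Box-Jenkins ARIMA modelling, fits a single-factor model of shared
    trial-to-trial excitability, compares encoding capacity under three
    relative-difference regimes, and tests cross-cluster correlation of
    predicted cortical state. Includes a synthetic session generator that
    emulates the assumed statistical structure (shared latent state,
    depressive adaptation, unreliable spiking, multi-cluster response
    distributions) and the four surrogate-control constructions used to
    calibrate the cluster and angle statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
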