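Package: clustpred
Title: Risk Prediction for Clustered Binary Data with Confounding by
    Cluster and Informative Cluster Size
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and validating risk prediction models on
    clustered binary outcomes when confounding by cluster (CBC) or
    informative cluster size (ICS) may be present. Provides a simulator for
    clustered data with configurable CBC/ICS mechanisms, cluster-specific
    (random-intercept logistic GLMM), marginal (GEE with exchangeable or
    independence working correlation) and conditional maximum likelihood
    model fitters with cluster-mean-of-exposure and cluster-size
    adjustments, conditional and marginal prediction engines (numerical
    integration over the random-effect distribution or the attenuation
    approximation), predictive-performance metrics (calibration in the
    large, calibration slope, C-statistic, root predictive mean squared
    error, Brier score), CBC/ICS diagnostics, and a simulation-study runner
    with cluster-level bootstrap internal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    sandwich,
    stats,
    utils,
    pracma,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
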