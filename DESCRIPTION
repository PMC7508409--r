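Package: streamdesign
Title: Pseudo-Bayesian Optimal and Adaptive Sampling Designs on Stream Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing where to monitor on dendritic stream networks.
    Implements geostatistical linear models with stream-specific tail-up and
    tail-down covariance components, hydrologic distance structures and
    confluence weights, maximum-likelihood and restricted maximum-likelihood
    fitting, universal kriging, and a pseudo-Bayesian design framework in
    which design-quality criteria (utility functions for parameter
    estimation, prediction and space filling) are averaged over log-normal
    priors on the covariance parameters by Monte-Carlo integration. Designs
    are optimised by a greedy coordinate-exchange algorithm with random
    restarts, with support for stepwise site removal, myopic adaptive
    (sequential) design with prior updating, spatially balanced and heuristic
    baseline designs, and a synthetic dendritic-network generator for fully
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
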