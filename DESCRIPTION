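Package: lassokalman
Title: Time-Varying Sparse Gene Regulatory Network Inference via
    LASSO-Kalman Smoothing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers time-varying, signed, sparse gene regulatory networks
    from short expression time series. Each gene's incoming-edge vector is
    modelled as a random-walk state observed through the linear expression
    model, tracked with a Kalman filter whose estimate is projected onto
    sparse vectors by an l1 (soft-thresholding) step at every epoch, and
    refined by a forward-backward smoother. The sparsity weight is chosen
    by generalized cross-validation and the tracker is initialized from a
    static l1-penalized network estimate. Includes a synthetic-data
    generator for sparse, slowly rewiring networks, edge-error and
    confusion-matrix evaluation, temporal topology statistics (degree
    trajectories, power-law exponent, clustering coefficient), TSV/SIF
    import/export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    parallel,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
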