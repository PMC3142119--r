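Package: interpuq
Title: Uncertainty Envelopes for Sparse Quantitative Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the uncertainty in the unmeasured intervals of sparse
    quantitative series (for example gene expression time courses) under a
    biologically motivated shape constraint: interpolations through the data
    may not contain more inflexion points than the measurements themselves
    imply. Provides plausible-interpolation bounds (including their extension
    over measurement-error confidence-limit corners), likelihood distributions
    of interpolations at guide points computed either by acceptance-rejection
    Monte Carlo or by a direct dynamic-programming pass over discretized
    columns, stratified (Latin Hypercube) propagation of replicate-based
    t-distribution measurement error, central likelihood envelopes at chosen
    levels, predictive-coverage evaluation by withholding time points, and
    first-principal-component summarization of genome-wide matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
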