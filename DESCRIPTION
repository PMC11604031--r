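Package: kldomain
Title: Domain Selection for Gaussian Process Data via Local Kullback-Leibler
    Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample comparison of Gaussian process data observed on a
    common discrete grid. Implements the closed-form Kullback-Leibler (KL)
    divergence between the finite-dimensional restrictions of two Gaussian
    processes, a sliding-window search for the contiguous sub-interval of
    the domain where the two processes diverge the most, shrinkage
    estimation of high-dimensional covariance matrices with cross-validated
    regularization, nonparametric bootstrap confidence intervals and sets
    for the selected interval, quadratic discriminant classification
    restricted to the selected interval, and a Monte Carlo simulation
    framework with Fourier-basis Gaussian process generators and the
    average integrated Jaccard distance as recovery metric. Includes
    readers for wide/long delimited curve data and UCR-style labeled
    time-series text, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
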