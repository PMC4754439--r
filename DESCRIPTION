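Package: hrvfractal
Title: Multifractal and Visibility-Graph Analysis of Heart-Rate Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear characterisation of heart-rate (BPM) time series with
    two chaos-based techniques: multifractal detrended fluctuation analysis
    (MF-DFA), yielding generalized Hurst exponents h(q), the mass exponent
    tau(q), the singularity spectrum f(alpha) and its width; and natural
    visibility graphs, yielding the power-law exponent of the degree
    distribution (PSVG). Includes exact-covariance fractional Gaussian noise
    and binomial-cascade generators with known scaling exponents for
    validation, shuffled surrogates, readers for PhysioNet-style two-column
    BPM text files, and a pre-versus-meditation comparison pipeline with
    percent-increase statistics and cross-method correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
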