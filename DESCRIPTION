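Package: causalts
Title: Time-Lagged Causal Discovery and Causal Effect Analysis for
    Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs lag-specific causal networks from multivariate
    time series such as ROI-averaged BOLD signals. Implements two-stage
    causal discovery (PC-style parent pre-selection followed by momentary
    conditional independence tests), pluggable conditional-independence
    tests (linear partial correlation with an analytic Student-t null, and
    a k-nearest-neighbour conditional mutual information estimator with a
    permutation null), linear causal-effect quantification via path
    coefficients and their accumulated impulse responses, mediated causal
    effects by path blocking, aggregate node measures (ACE, ACS, AMCE),
    decomposed transfer entropy with graph-derived condition sets, and a
    ground-truth synthetic generator of stable lagged linear stochastic
    processes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
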