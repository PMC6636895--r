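Package: lscggm
Title: Latent Sparse Conditional Gaussian Graphical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure learning for Gaussian conditional random fields in the
    presence of unobserved confounders. Estimates a sparse conditional precision
    matrix over outputs given inputs while absorbing latent effects into a
    low-rank component, by penalized maximum likelihood with an l1 plus nuclear
    norm penalty. Provides an ADMM solver with an inexact proximal step for the
    constrained stacked nuclear norm, a high-accuracy first-order oracle and a
    semidefinite-program export of the objective, baseline estimators (sparse
    conditional model, low-rank plus sparse decomposition, graphical lasso),
    a structured simulator of chain graphs with block latent and input designs,
    precision/recall evaluation of support recovery, and complementary-pairs
    stability selection with expected-false-discovery control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
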