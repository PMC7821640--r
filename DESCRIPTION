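Package: oplsr
Title: Feature Selection from Orthogonal PLS Regression Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variable selection for spectral and omics data (NIR, LC-MS,
    NMR) through orthogonal partial least squares regression. Direct
    orthogonal signal correction removes from the predictor matrix the
    systematic variation orthogonal to the response; PLS regression on the
    corrected matrix yields regression vectors whose per-variable
    coefficients are tested against permutation-based empirical null
    distributions, with a correlation pre-filter and an optional
    Bonferroni correction. Includes a three-layer collinear benchmark
    generator, false-discovery-rate and lasso baseline selectors,
    train/test evaluation metrics (MSE, Q-squared, precision), tidy
    accessors, plotting helpers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
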