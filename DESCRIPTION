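Package: leupmosaic
Title: Entropy-Based Analysis of Photoreceptor Mosaic Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cone photoreceptor mosaics with the Least
    microEnvironmental Uncertainty Principle (LEUP). Predicts cone-type
    proportions from nearest-neighbour-distance fluctuations via a
    one-parameter maximum-entropy distribution fitted by Kullback-Leibler
    minimisation, quantifies the thermodynamic robustness of tissue
    differentiation through a fluctuation-theorem inequality, maps
    entropy-production landscapes over the cell sensing radius, relates
    nearest-neighbour variance to sensing radii and hyperuniformity
    exponents, and generates synthetic typed point patterns (jittered
    lattices, Poisson, hard-core) with estimators so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
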