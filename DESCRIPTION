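Package: netkat
Title: Pathway-Integrated Kernel Association Tests with Graph Laplacian
    Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Kernel machine score tests for association between a continuous
    phenotype and a pathway of molecular features (metabolites, proteins,
    genes), with pathway topology injected into a Gaussian kernel through the
    regularized normalized graph Laplacian.  Provides the pathway-free and
    plain-Laplacian variants of the test, a principal-component F-test and a
    minimum-Simes competitor, weighted chi-square tail probabilities by
    characteristic-function inversion with a moment-matching fallback, and a
    simulation framework for type I error and power under incomplete or
    incorrect pathway knowledge.  Reads feature tables, covariate tables, GMT
    pathway membership and per-pathway edge lists, and exposes a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
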