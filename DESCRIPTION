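Package: methlv
Title: Knowledge-Constrained Latent-Variable Analysis of DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compresses CpG probe-level beta values into transcript-wise
    features by windowed probe selection and per-transcript principal
    component analysis, fits a knowledge-constrained non-negative matrix
    factorization in which the latent feature matrix is regularized toward a
    sparse combination of gene-set indicator columns, and transfers a frozen
    latent matrix onto new cohorts to obtain comparable sample loadings.
    Includes downstream loading-matrix analyses (Ward hierarchical
    clustering, Hartigan-Wong k-means, UMAP embedding, per-latent-variable
    differential tests with Benjamini-Hochberg adjustment, two-group
    log-rank tests, differentially methylated position calling), conversion
    of per-CpG bisulfite calls to array probe-wise betas, and synthetic data
    generators with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    uwot
Suggests:
    testthat (>= 3.0.0),
    clue,
    cluster,
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
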