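Package: genemask
Title: Gene Masking: Genetic-Algorithm Wrapper Feature Selection for
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional gene-expression
    matrices via a binary-encoded genetic algorithm ("gene masking").
    Candidate feature subsets are encoded as binary masks and scored by a
    weighted fitness combining k-fold cross-validated accuracy of a
    nearest-centroid or nearest-shrunken-centroid classifier with the
    fraction of genes eliminated. Includes the centroid classifiers with
    soft-threshold shrinkage, a stratified cross-validation fitness engine,
    an exhaustive-search oracle for small problems, a parameter-tuning grid
    over the fitness weight and genetic-operator rates, multi-run
    gene-occurrence reporting, and a synthetic data generator with planted
    informative genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
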