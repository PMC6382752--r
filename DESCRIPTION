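Package: dirichletLRT
Title: Dirichlet Likelihood-Ratio Tests for Microbial Community and
    Gene-Class Composition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tests whether the composition of a multitype population
    (bacterial phyla, antimicrobial-resistance gene classes, or any
    sample-by-class proportion table) differs between treatments or
    environments. Compositions are modelled as draws from environment-
    specific Dirichlet distributions and compared with a likelihood-ratio
    test, using either the asymptotic chi-squared reference or a
    label-permutation randomization reference suited to small sample
    sizes. Includes a simulation-based goodness-of-fit check for the
    Dirichlet model, power estimation for designing future experiments,
    class-inclusion preprocessing (ever-present and minimum-proportion
    rules with aggregation into an "other" class), a synthetic-data
    generator with known parameters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
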