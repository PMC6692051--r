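Package: primacode
Title: Primacy Coding in Olfactory Receptor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation and analytical statistical theory of
    primacy coding, where an odor is represented by the identities of the
    N_C most strongly excited olfactory receptor types.  Provides a
    parametric odor environment (Bernoulli presence, log-normal
    concentrations), log-normal and log-uniform receptor sensitivity
    ensembles with per-receptor sensitivity factors, primacy / binary /
    normalized coding schemes, entropy and coding-capacity estimators,
    perfect-decoder identification bounds, closed-form discrimination
    theory based on log-normal excitation statistics and order
    statistics, and seeded figure-class experiment pipelines with a thin
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
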