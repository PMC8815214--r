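Package: epstrat
Title: Mixed-Model Association Testing Under Extreme Phenotype Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and association-testing toolkit for evaluating how
    mixed-model corrections for population stratification behave under
    extreme phenotype sampling (EPS), where genotypes are collected only on
    individuals in the tails of a quantitative phenotype and tail membership
    is analysed as a binary trait. Provides Balding-Nichols and two-deme
    structured-coalescent genotype simulators, phenotype generation with
    subpopulation mean shifts and extreme-tail ascertainment, a standardized
    genetic relationship matrix with principal components, and from-scratch
    implementations of the association methods being compared: a linear
    mixed model with spectral REML, a logistic mixed model fitted by
    penalized quasi-likelihood with average-information REML plus
    single-variant score tests and the burden/SKAT/SKAT-O/efficient-hybrid
    rare-variant set tests, a liability-threshold method based on a
    ridge-regularized probit fit, and principal-component-corrected and
    uncorrected logistic regression baselines. An experiment harness
    estimates type I error and power with Monte-Carlo standard errors and
    produces QQ-plot data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
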