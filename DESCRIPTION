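Package: mrpath
Title: Two-Sample Mendelian Randomization and Mediation Analysis for
    Molecular Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a complete two-sample Mendelian randomization (MR)
    workflow for quantifying how much of an exposure's effect on a binary
    disease outcome is mediated by intermediate molecular traits. Provides
    GWAS summary-statistic reading and allele harmonization, instrument
    construction (genome-wide significance selection, greedy LD clumping,
    cis windows), five univariable causal estimators (Wald ratio,
    inverse-variance weighted, correlation-adjusted IVW, MR-Egger, weighted
    median and weighted mode) with heterogeneity, leave-one-out and Steiger
    directionality diagnostics, multivariable MR with conditional
    F-statistics, product-of-coefficients mediation with delta-method
    standard errors for the proportion mediated, and an individual-level
    summary-statistics simulator with known causal, pleiotropic, linkage,
    sample-overlap and winner's-curse structure for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
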