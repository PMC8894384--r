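Package: overallgene
Title: Gene-Based Association Tests from GWAS Summary Statistics with
    eQTL-Derived Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based association testing from per-variant GWAS summary
    statistics (Z-scores), a linkage-disequilibrium (LD) reference matrix, and
    one or more eQTL-derived variant weight sets.  Implements weighted burden,
    SKAT and SKAT-O statistics with exact weighted-chi-square tail
    probabilities, maximum-likelihood shrinkage regularization of
    reference-panel LD, estimation of the null correlation among the combined
    tests by replication, and an omnibus p-value via the extended Simes
    procedure, together with Cauchy-combination, S-PrediXcan and S-TWAS
    comparators.  Ships a self-contained simulator (synthetic LD, haplotype
    pools, expression weights, phenotypes) that drives type-I-error and power
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
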