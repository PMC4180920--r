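Package: multilineGP
Title: Multi-Line Genomic Prediction with Linear and Bayesian Marker Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation of genomic prediction across related and
    distant breeding lines. Provides a multi-line gene-dropping simulator for
    genotypes, pedigree and polygenic phenotypes; SNP quality-control rules
    (call rate, minor allele frequency, missing homozygotes, Hardy-Weinberg
    chi-square); pedigree (numerator) and three genomic relationship matrices;
    a unified fitting front-end for pedigree BLUP, GBLUP, ridge-regression BLUP
    (RRBLUP), principal-component ridge regression (RRPCA) and the Gibbs-sampling
    variable-selection models BayesC and BSSVS; and validation-based evaluation of
    prediction accuracy, its approximate standard error and bootstrap dispersion
    bias, together with a scenario runner that crosses target lines with all
    single- and multi-line training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
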