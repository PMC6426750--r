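Package: gsfactors
Title: Benchmarking Factors that Affect Genomic Prediction Accuracy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic selection toolkit for benchmarking the factors that
    drive prediction accuracy: additive and additive-plus-dominance GBLUP
    with VanRaden and Aliloo genomic relationship matrices and
    average-information REML, a Gibbs-sampling implementation of the BayesR
    four-component normal-mixture model for SNP effects, replicated k-fold
    cross-validation with nested marker-density subsampling and minor allele
    frequency experiments, genotype quality control (MAF, call rate,
    Hardy-Weinberg), readers for VCF, PLINK binary and dosage tables, and a
    simulator for genotypes and quantitative traits of controlled
    heritability and genetic architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    withr,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
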