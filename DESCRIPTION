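Package: gxewas
Title: Environment-Dependent GWAS of Plastic Traits with Animal Models
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for genome-wide association analysis of a
    phenotypically plastic trait under genotype-by-environment interaction.
    Implements a repeated-measures animal model fitted by restricted maximum
    likelihood (REML) with a pedigree numerator relationship matrix,
    permanent-environment effects, SNP and SNP-by-environment fixed effects,
    and residual variances stratified by environmental class. Includes
    genotype and individual quality control, spring-temperature window
    classification of years into terciles, identity-by-state relatedness and
    multidimensional scaling outlier detection, an effective-number-of-tests
    multiple-testing correction under linkage disequilibrium, genomic
    inflation diagnostics, marginal r-squared model comparison, and a
    synthetic-data generator (pedigree, linked genotypes, temperatures,
    phenotypes) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
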