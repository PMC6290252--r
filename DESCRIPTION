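Package: qtlallele
Title: Multi-Allelic SNPLDB Markers, Two-Stage Multi-Locus Association and
    QTL-Allele Based Cross Prediction for Inbred Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting quantitative traits in inbred germplasm
    panels with multi-allelic haplotype-block markers. Groups tightly linked
    SNPs into linkage-disequilibrium blocks whose haplotypes act as alleles,
    fits a restricted two-stage multi-locus association model with
    population-structure eigenvector covariates, estimates variance
    components, heritability and the genetic coefficient of variation for
    multi-environment randomized-complete-block trials, assembles the
    QTL-allele matrix of a panel, tests allele-frequency differentiation
    among subpopulations, predicts optimal crosses from simulated
    recombinant inbred progeny under linkage and independent-assortment
    models, and filters candidate genes near detected loci. Includes a
    synthetic-population generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    ape,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
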