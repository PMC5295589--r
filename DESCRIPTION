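Package: sparkqtl
Title: QTL Mapping of Sparkling-Wine Second-Fermentation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative-genetics workflow for in-bottle (second)
    fermentation of sparkling wine in a Saccharomyces cerevisiae F1 cross:
    temperature normalisation of CO2 pressure curves and five-parameter
    logistic (5PL) kinetic fitting; genotype calling of segregants from
    low-coverage allele counts at parental SNPs; marker-map construction
    with segregation-distortion and spacing filters; Wilcoxon rank-sum
    genome scans with permutation-based genome-wide thresholds and QTL
    interval calling; and cross-level statistics (mid-parent heterosis,
    broad-sense heritability, transgressive segregation, ANOVA variance
    decomposition with QTL interactions, Duncan multiple-range grouping,
    and allele-by-pH genotype-environment analysis). A synthetic-cross
    generator with known ground truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    jsonlite,
    car,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
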