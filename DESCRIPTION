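Package: traitpop
Title: Trait-Linked Population Genomics and Expression Analysis from RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking RNA-seq derived genotypes and cardiac gene
    expression to population origin, exercise regime and swimming performance in
    Atlantic salmon. Implements genotype calling and locus filtering from allele
    read depths, group allele frequencies and chi-square heterogeneity tests,
    simple-matching dissimilarity and neighbour-joining relatedness trees, an
    FST-decomposition outlier scan fitted by reversible-jump MCMC with a
    beta-binomial likelihood, negative-binomial differential expression with
    empirical-Bayes dispersion and fold-change shrinkage, Yates-corrected
    category enrichment, and SNP-by-expression integration. A synthetic-data
    module generates allele-count tables and expression matrices with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    readr,
    stringr,
    ggplot2,
    ape,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    DESeq2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
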