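Package: hybridplan
Title: Design of Inbred Lines and F1 Hybrids from Biallelic SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning inbred-line and F1-hybrid breeding programmes
    in outcrossing leafy crops such as leaf chicory (radicchio) from a
    biallelic SNP genotype matrix. Implements per-population diversity
    statistics (observed/effective alleles, heterozygosity, fixation index,
    polymorphic and private alleles), Wright's F-statistics and island-model
    gene flow, distance-based analysis of molecular variance (AMOVA) with a
    label-permutation test, simple-matching genetic similarity with UPGMA
    clustering and principal coordinate analysis, Evanno delta-K model choice
    from admixture-run log-likelihoods, Mendelian prediction of expected
    progeny heterozygosity under selfing, full-sibling and pairwise-crossing
    strategies with greedy parental selection, and an in-silico CAPS assay
    (virtual PCR, restriction digestion, band-pattern genotype calling) for a
    nuclear male-sterility locus. A seeded synthetic-cohort generator
    (Balding-Nichols divergence, sib-mating, admixture, missing data) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    magrittr,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
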