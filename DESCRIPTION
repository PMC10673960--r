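Package: snailmap
Title: Linkage Maps and Binary-Trait QTL Mapping for Full-Sib Snail Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Construction of genetic linkage maps from a full-sib cross and
    binary-trait mapping of Mendelian shell-polymorphism loci, built around the
    design of a Cepaea nemoralis laboratory cross (two parents, two
    grandparents, 75 offspring) segregating for the dominant pink-over-yellow
    shell ground colour locus and the dominant mid-banded locus. Provides a
    synthetic cross simulator with ground truth (Haldane map function,
    crossover counts Poisson per meiosis, genotyping error, missingness and
    negative-binomial read depth), a VCF marker-retention cascade, two-point
    recombination/LOD estimation with single-linkage grouping and seriation
    ordering, LOD-matrix pruning and contig-conflict resolution, sex-averaged
    map statistics (expected genome length, coverage, genome-wide
    recombination rate), a hidden-Markov-model genotype-probability engine with
    logistic-regression genome scans, permutation thresholds, Bayes credible
    intervals, allele effects and Mendelian segregation-pattern validation,
    and a noncentral chi-square power calculation for detecting a trait locus
    within a candidate interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
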