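Package: dscan
Title: D-Statistic Introgression Tests and Genome-Wide Tree-Discordance Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying reticulate evolution from
    whole-genome data in small multi-species panels. Implements outgroup-polarized
    ABBA-BABA site-pattern counting with the D statistic, weighted block-jackknife
    standard errors, Bonferroni control over all quartet configurations, and
    admixture-fraction estimation; callable-site selection from pileup-level
    depth and quality filters, fixed-size genomic-bin acceptance, chaining and
    multi-sample intersection; per-allele effective-coverage filtering for
    high-variance organellar data; gene-tree analytics (neighbor-joining trees,
    bootstrap, clade frequencies, extended majority-rule consensus, STAR species
    trees, Robinson-Foulds distances); and windowed genome scans with Kendall
    rank correlations against recombination-rate tracks. A bundled
    multispecies-coalescent simulator with directed admixture pulses and
    pileup-level artifact injection makes every stage testable end to end on
    synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    withr
Config/testthat/edition: 3
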