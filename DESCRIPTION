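Package: divscan
Title: Windowed Genome Divergence Scans with Coalescent Nulls and
    Demographic Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome divergence between a pair of closely
    related species from resequencing data: per-window population-genetic
    statistics (Weir-Cockerham FST, nucleotide diversity, Watterson's theta,
    Tajima's D, Fay and Wu's H, dxy, relative node depth, linkage
    disequilibrium), a two-population isolation-with-migration coalescent
    simulator with recombination and a sequencing read layer, joint 2D site
    frequency spectrum construction with composite-likelihood demographic
    model fitting and AIC-based model choice, and simulation-based empirical
    P-values with Benjamini-Hochberg FDR control for detecting windows of
    exceptionally high or low differentiation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
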