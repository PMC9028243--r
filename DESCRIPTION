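Package: phyloccs
Title: Convergent Substitutions, Selection and Gene-Family Evolution on
    Bird Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics toolkit for detecting convergent
    amino-acid substitutions at conserved sites (CCS) in foreground
    lineages, built around a seven-species tactile-foraging bird study
    design. Provides Markov clustering of protein similarity graphs into
    ortholog families with per-species category tallies, marginal
    ancestral sequence reconstruction under JTT with discrete-gamma rate
    variation, branch-site and two-ratio codon models of positive
    selection with likelihood-ratio tests, Nei-Gojobori dN/dS counting,
    equal-rate birth-death modelling of gene-family size evolution with
    family-wide and per-branch Viterbi p-values, hypergeometric
    enrichment with Benjamini-Hochberg FDR, a random-trio false-positive
    control for convergence calls, and seeded simulators that generate
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
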