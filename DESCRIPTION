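Package: rershift
Title: Convergent Evolutionary Rate Shifts for Binary Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relative evolutionary rates (RER) analysis for convergent binary
    phenotypes on a fixed species phylogeny. Computes per-element relative
    rates from branch lengths with a mean-variance correction, regresses out a
    continuous confounder such as body size, tests rate-phenotype association
    with Kendall's tau, and calibrates p-values with phylogenetically
    constrained phenotype permutations ("permulations"). Includes
    Jeffreys-Zellner-Siow Bayes factors to disentangle confounded phenotypes,
    rank-based geneset enrichment with an AUC statistic, per-species rate-shift
    tests, a conserved noncoding element construction pipeline, and a synthetic
    data generator with planted rate shifts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
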