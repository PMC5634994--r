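Package: mfclone
Title: Clonal Origin, Heterogeneity and Driver Analysis for Multifocal Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-focal, multi-region tumor sequencing
    data. Decides whether co-occurring tumors in one patient are independent
    primaries or clonally related (hypergeometric variant-overlap test),
    reconstructs maximum-parsimony phylogenies from binary mutation matrices
    with trunk/branch assignment and the branched-to-truncal index, builds
    96-channel trinucleotide mutation spectra and refits signature exposures
    by non-negative least squares with iterative pruning, estimates per-variant
    cancer cell fractions from allele counts, purity and local copy number with
    exact binomial confidence intervals and a clonal/subclonal call, screens
    putative driver mutations with a census-gated rule engine, enumerates
    9-11-mer mutant peptides and applies an affinity-based neoantigen filter.
    Includes a synthetic-cohort simulator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ape,
    pracma,
    yaml,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
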