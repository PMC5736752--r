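Package: platsig
Title: Mutational Signature Analysis for Paired Pre- and Post-Chemotherapy Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds trinucleotide-context mutation catalogs (96 and
    transcription-stranded 192 channels) from somatic SNV tables and a
    reference sequence, discovers mutational signatures by multi-run
    non-negative matrix factorization with multiplicative (Brunet) updates
    and minimum-residual run selection, infers activities of a fixed
    signature set with a windowed asymptote stopping rule, renormalizes
    signatures between genomes/exomes by trinucleotide frequency ratios,
    tests signature similarity by activity substitution with permutation
    null distributions, tests transcriptional strand bias with exact
    binomial tests, attributes per-mutation credit to signatures weighted
    by clonality, and computes intratumoral heterogeneity metrics for
    paired pre-/post-treatment tumor cohorts. Includes a seeded synthetic
    cohort generator with planted signature mixtures, subclone cancer cell
    fraction structure, strand bias, and a sequencing-depth detection
    model, so the whole chain is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
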