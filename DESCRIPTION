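Package: orthodiverge
Title: Ortholog Divergence, Ka/Ks Selection Screens and Neutral Rate
    Calibration for Transcriptome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative molecular-evolution toolkit for pairs of
    transcriptomes. Identifies putative orthologs between two coding
    sequence sets by reciprocal best hit with bit-score and annotation
    concordance filters, builds gap- and stop-free pairwise codon
    alignments, estimates Ka, Ks and their ratio with a Nei-Gojobori
    pathway-counting estimator and a kappa- and codon-frequency-corrected
    estimator in the Yang-Nielsen spirit, screens pairs for positive
    selection with a synonymous-divergence paralog cutoff, calibrates a
    neutral substitution rate against a divergence time, and applies
    post-calling filters to two-group transcriptome SNP tables. A codon
    substitution simulator with known truth (omega, kappa, branch length)
    generates every input the pipeline consumes, so estimator recovery
    can be tested end to end without external data or search tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
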