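Package: BayesHLA
Title: Noise-Tolerant Bayesian HLA Typing from Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Assigns the pair of HLA alleles of a sample from error-prone
    long-read circular-consensus amplicon reads using a Bayesian genotype
    likelihood, with a trimmed-likelihood variant that tolerates reads
    misassigned between samples by barcode-calling errors. Includes the
    supporting pipeline: construction of per-locus allele target panels from
    IMGT-style coding-sequence alignments, a CCS read simulator with a
    configurable length/accuracy/error-mix model, affine-gap local alignment
    and exon-aware read trimming, allele and read filters, a MaxTwo baseline
    caller, and an experiment harness for multiplexing designs, noise sweeps
    and homozygous-versus-heterozygous contingency analysis.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
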