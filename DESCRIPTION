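Package: contigqc
Title: Quality Assessment of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating de novo transcriptome assemblies of
    short-read (Illumina) data without a reference genome. Implements
    indirect quality measures based on homology-hit counts at dual
    E-value cutoffs and unique-gene (UniGen) redundancy reduction, and a
    direct assessment against a small trusted reference gene set (e.g. a
    mitochondrial gene complement): per-gene coverage by merged alignment
    intervals, pooled multi-assembly coverage, and diagnosis of assembly
    defects (chimeric contigs, residual sequencing-adapter extensions,
    redundancy clusters). Also provides pileup-based classification of
    sites into SNPs versus sequencing errors for pooled-sample data,
    perfect microsatellite (SSR) detection, contig length/coverage
    statistics, and a truth-labelled synthetic data generator for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
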