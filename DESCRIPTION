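Package: repeatscope
Title: Tandem-Repeat Expansion Genotyping from Targeted Long-Read Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes tandem-repeat expansion alleles at the FGF14
    intron-1 locus (SCA27B) from targeted long-read amplicon sequencing.
    Implements the full path from raw nanopore-like FASTQ reads to per-allele
    repeat counts: quality filtering, double-flank anchoring with
    edit-tolerant 25-mer matching, strand resolution, repeat-motif
    decomposition into classified triplets, interruption typing, allele
    partitioning and genotype classification against pathogenicity
    thresholds. Also provides somatic-mosaicism statistics, quantile-based
    outlier screening of short-read repeat estimates with PPV/sensitivity
    evaluation, cohort-level size-bin enrichment statistics, and a synthetic
    read generator that emulates the locus architecture and nanopore error
    processes so that every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
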