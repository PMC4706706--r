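Package: rvstore
Title: An Embeddable Reference Variant Store with Reversible Sortable
    Variant Keys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Normalizes small genetic variants (SNVs, MNVs, indels) against a
    reference genome, assigns each a globally unique, reversible,
    lexicographically sortable base-64 key, and registers variants from
    multiple sequencing studies with per-study source tracking, quality
    (pass) flags, and subpopulation allele frequencies.  On top of the
    registry it provides the cohort analyses a curated variant store is
    typically used for: binning clinically asserted variants by maximum
    ethnicity-specific allele frequency, flagging pathogenic-but-common
    variants in healthy populations, discovering variants exclusive to a
    disease cohort, and exact-test screening for allele-frequency
    differences between cohorts.  A deterministic simulator generates
    reference FASTA, multi-study VCFs and clinical assertion tables so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
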