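Package: radsig
Title: Genomic Signatures of Ionizing Radiation in Tumour Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies the two tumour-type-independent genomic
    signatures of ionizing radiation exposure: an excess of small (1-100 bp)
    deletions that carry junction microhomology and are distributed uniformly
    across the genome, and an excess of balanced inversions recovered by
    pairing reciprocal head-to-head and tail-to-tail rearrangement junctions.
    Provides readers for somatic variant catalogues (VCF, BEDPE, BED,
    bedGraph, FASTA), the balanced-inversion screen with its read-support and
    size filters, deletion burden and size-spectrum metrics, breakpoint
    microhomology computation from the reference, mutation-density association
    tests against genomic features with Benjamini-Yekutieli control, clonality
    classification from mutation copy number, cohort-level mixed-effects and
    count-regression models, and a fully seeded synthetic-cohort generator
    with machine-readable ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    lme4,
    lmerTest,
    glmnet,
    vcfR,
    Biostrings,
    IRanges,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
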