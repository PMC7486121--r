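Package: annoforge
Title: Audit, Compare and Curate Transcriptome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quality control and curation of GTF transcriptome
    annotations. Audits coding genes for 3' UTR and stop-codon completeness,
    matches genes across annotations by anchoring on terminal 3' UTR exons,
    detects genes missing from one annotation via intron-chain transcript
    matching with gffcompare-style class codes, and mechanizes a merge-and-
    curate workflow: fusion-transcript removal, small-RNA filtering,
    nomenclature reconciliation, missing-gene add-back, stable gene ID
    assignment and novel-locus triage. Includes a deterministic synthetic
    annotation generator with a planted-discrepancy manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
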