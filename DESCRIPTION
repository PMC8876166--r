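Package: mscmir
Title: Integrative Transcriptome and miRNome Comparison of Mesenchymal Stromal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-group comparison of bulk transcriptome (FPKM) and miRNome (TPM)
    profiles of tissue-resident mesenchymal stromal cells: low-expression
    filtering, per-feature Welch differential expression, transcript-to-gene
    collapsing, direction-consistent integration of validated miRNA-target
    interactions, gated hypergeometric gene-set enrichment with GO-circle
    z-scores, in-silico secretome partitioning, marker-overlap Fisher testing,
    and qPCR relative expression by the 2^(-DeltaCt) method. Includes a seeded
    generator of coupled transcriptome/miRNome datasets with ground truth so
    the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
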