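Package: clonmem
Title: Clonal Epigenetic Memory Analysis for Lineage-Traced Single-Cell Multiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying heritable (clonal) epigenetic memory in
    lineage-barcoded single-cell multiome (ATAC + RNA) experiments: expressed
    clonal-barcode parsing and edit-distance consensus clone calling, background-
    matched deviation scores for motif families and gene expression programs, a
    clonal-variance permutation test for heritability of single-cell scores,
    k-nearest-neighbour condition enrichment in latent embeddings, transcription-
    factor footprint memory calls with co-binding odds-ratio statistics, and
    spatial tumor segmentation with program scoring on binned spatial
    transcriptomics. Includes a synthetic-data generator that plants known clonal
    structure, condition memory effects, footprint co-occurrence and tumors so the
    whole pipeline can be validated end-to-end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    tibble,
    purrr,
    stringr,
    rlang,
    ggplot2,
    igraph,
    generics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
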