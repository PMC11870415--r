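#' Write simulated datasets to plain-text interchange files
#'
#' Exports the simulator outputs in the formats the pipeline consumes
#' elsewhere: cell/feature tables as TSV, count matrices as MatrixMarket
#' (`.mtx` plus row/column name TSVs), peak intervals as 0-based half-open
#' BED, and the planted truth as JSON. Requires the `readr` and `jsonlite`
#' packages.
#'
#' @param multiome Output of [simulate_multiome()].
#' @param dir Output directory (created if needed).
#' @param reads Optional output of [simulate_barcode_reads()].
#' @param footprints Optional output of [simulate_footprints()].
#' @param spatial Optional output of [simulate_spatial()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(multiome, dir, reads = NULL, footprints = NULL,
                             spatial = NULL) {
  rlang::check_installed(c("readr", "jsonlite"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)

  readr::write_tsv(multiome$cells, p("cells.tsv"))
  readr::write_tsv(multiome$peaks, p("peaks.bed"), col_names = FALSE)
  write_mtx(multiome$counts_peaks, p("counts_peaks"))
  write_mtx(multiome$counts_genes, p("counts_genes"))
  fam <- as_tibble(as.matrix(multiome$peak_annotation), rownames = "peak_id")
  readr::write_tsv(fam, p("families.tsv"))
  topics <- as_tibble(multiome$topic_weights, rownames = "gene")
  readr::write_tsv(topics, p("topics.tsv"))

  truth <- list(clone_truth = multiome$clone_truth)
  if (!is.null(reads)) {
    readr::write_tsv(reads$reads, p("barcode_reads.tsv"))
    truth$consensus <- as.list(reads$consensus)
  }
  if (!is.null(footprints)) {
    readr::write_tsv(footprints, p("footprints.tsv"))
  }
  if (!is.null(spatial)) {
    readr::write_tsv(spatial$bins, p("spatial_bins.tsv"))
    write_mtx(spatial$counts, p("counts_spatial"))
    truth$tumors <- spatial$tumors
    truth$program_genes <- spatial$program_genes
  }
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_mtx <- function(m, stem) {
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(rownames(m), paste0(stem, ".rows.tsv"))
  writeLines(colnames(m), paste0(stem, ".cols.tsv"))
}

#' Read a MatrixMarket count matrix with dimension names
#'
#' Counterpart of the matrices written by [write_simulation()].
#'
#' @param stem Path stem (reads `<stem>.mtx`, `<stem>.rows.tsv`,
#'   `<stem>.cols.tsv`).
#' @return A sparse dgCMatrix with dimnames.
#' @export
read_mtx <- function(stem) {
  m <- methods::as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(stem, ".rows.tsv")),
                      readLines(paste0(stem, ".cols.tsv")))
  m
}
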