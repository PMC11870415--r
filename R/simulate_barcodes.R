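# Barcode geometry shared by the simulator and the parser: a 48-bp variable
# region with invariant dinucleotides at fixed 0-based offsets.
barcode_invariant_offsets <- c(4L, 10L, 16L, 22L, 28L, 34L, 40L, 46L)
barcode_invariant_dinucs <- c("CT", "AC", "TC", "GT", "TG", "CA", "AT", "GC")
barcode_length <- 48L
dna_bases <- c("A", "C", "G", "T")

#' Generate planted clone consensus barcodes
#'
#' Draws 48-bp barcodes uniformly over the 32 random positions with the
#' invariant dinucleotides forced at their fixed offsets, rejecting candidates
#' whose Levenshtein distance to an already accepted barcode is below
#' `min_distance`. The default minimum of 9 guarantees that distance-4
#' consensus clustering can never merge two planted clones.
#'
#' @param n Number of barcodes.
#' @param min_distance Minimum pairwise Levenshtein distance.
#' @return Character vector of `n` barcodes.
#' @examples
#' make_clone_barcodes(3)
#' @export
make_clone_barcodes <- function(n, min_distance = 9L) {
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L * n) {
      abort("could not place clone barcodes at the requested minimum distance.")
    }
    cand <- random_barcodes(1L)
    if (length(out) == 0 || min(adist(cand, out)) >= min_distance) {
      out <- c(out, cand)
    }
  }
  out
}

random_barcodes <- function(n) {
  block <- function(dinuc) {
    rand <- matrix(sample(dna_bases, 4L * n, replace = TRUE), n, 4L)
    paste0(rand[, 1], rand[, 2], rand[, 3], rand[, 4], dinuc)
  }
  blocks <- lapply(barcode_invariant_dinucs, block)
  do.call(paste0, blocks)
}

#' Simulate expressed clonal-barcode reads
#'
#' Emits sequencing reads of each cell's clone consensus barcode: per cell,
#' `n_umis_per_cell` UMIs each sequenced `reads_per_umi` times. Reads carry a
#' short random stagger, the TAGACAT anchor, the 48-bp barcode with i.i.d.
#' per-base substitution errors at `barcode_error_rate`, and a fixed
#' downstream adapter. A `junk_fraction` of reads is replaced with junk
#' (broken anchor or all-G UMI, equiprobably).
#'
#' @param clone_truth Tibble with columns `cell` and `clone` (e.g. the
#'   `clone_truth` element of [simulate_multiome()]).
#' @param config A [simulation_config()].
#' @return A list: `reads` (tibble `cell_barcode`, `umi`, `read_sequence`),
#'   `consensus` (named character vector, clone -> planted 48-mer).
#' @examples
#' sim <- simulate_multiome(simulation_config(
#'   seed = 1, n_samples = 1, n_cells_per_sample = 10,
#'   n_peaks = 50, n_genes = 50, n_clones_per_sample = 2))
#' rd <- simulate_barcode_reads(sim$clone_truth, sim$config)
#' head(rd$reads)
#' @export
simulate_barcode_reads <- function(clone_truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(clone_truth) == 0) abort("`clone_truth` is empty.")
  if (config$barcode_error_rate >= 0.5) {
    abort("`barcode_error_rate` >= 0.5: clone recovery undefined.")
  }
  cfg <- config
  set.seed(artifact_seed(cfg, 2L))

  clones <- sort(unique(clone_truth$clone))
  consensus <- setNames(make_clone_barcodes(length(clones),
                                            cfg$min_consensus_distance),
                        clones)

  n_cells <- nrow(clone_truth)
  n_umis <- cfg$n_umis_per_cell
  n_reads_per_umi <- cfg$reads_per_umi
  reads_per_cell <- n_umis * n_reads_per_umi
  n_reads <- n_cells * reads_per_cell

  cell_barcode <- rep(clone_truth$cell, each = reads_per_cell)
  clone_of_read <- rep(clone_truth$clone, each = reads_per_cell)

  umi_per_cell <- random_kmers(n_cells * n_umis, 10L)
  umi <- rep(umi_per_cell, each = n_reads_per_umi)

  # barcode with per-base substitution errors
  bar <- consensus[clone_of_read]
  chars <- matrix(unlist(strsplit(bar, "", fixed = TRUE), use.names = FALSE),
                  nrow = n_reads, byrow = TRUE)
  err <- matrix(runif(n_reads * barcode_length) < cfg$barcode_error_rate,
                n_reads, barcode_length)
  idx <- which(err)
  if (length(idx)) {
    old <- chars[idx]
    # substitute with one of the three other bases, uniformly
    offs <- sample.int(3L, length(idx), replace = TRUE)
    pos <- match(old, dna_bases)
    chars[idx] <- dna_bases[((pos - 1L + offs) %% 4L) + 1L]
  }
  bar_seq <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))

  stagger_n <- sample(0:3, n_reads, replace = TRUE)
  stagger <- vapply(stagger_n, function(k) {
    if (k == 0) "" else paste(sample(dna_bases, k, replace = TRUE), collapse = "")
  }, character(1))
  anchor <- rep(trace_anchor, n_reads)
  adapter <- "ATCATCAAGATCGGAAGAGCGTCGTG"

  # junk reads: broken anchor (2 substitutions) or all-G UMI
  if (cfg$junk_fraction > 0) {
    junk <- runif(n_reads) < cfg$junk_fraction
    kind <- runif(n_reads) < 0.5
    anchor[junk & kind] <- "TCGCCAT"  # Hamming distance 2 from TAGACAT
    umi[junk & !kind] <- strrep("G", 10L)
  }

  reads <- tibble(
    cell_barcode = cell_barcode,
    umi = umi,
    read_sequence = paste0(stagger, anchor, bar_seq, adapter)
  )
  list(reads = reads, consensus = consensus)
}

random_kmers <- function(n, k) {
  m <- matrix(sample(dna_bases, n * k, replace = TRUE), n, k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
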