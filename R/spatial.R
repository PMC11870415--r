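#' QC, normalise and PC-smooth a binned spatial expression matrix
#'
#' Filters bins to a minimum read depth, scales each bin to the mean depth of
#' the remaining bins, log2(x+1)-transforms, runs PCA and smooths each gene
#' by averaging over every bin's `k` nearest neighbours in top-PC space
#' (the bin itself counts as one of the `k`).
#'
#' @param counts Sparse bin x gene count matrix with bin rownames.
#' @param bins Optional tibble `bin_id`, `x`, `y` carried through (filtered
#'   to QC-passing bins).
#' @param min_reads Minimum reads per bin (default 300).
#' @param n_pcs Number of principal components (default 20).
#' @param k Smoothing neighbourhood size (default 20).
#' @return An object of class `"spatial_smooth"`: list with `smoothed` and
#'   `normalized` (bin x gene matrices), `pcs` (bin x PC scores), `bins`
#'   (QC-passing bin tibble, when given) and `depth`.
#' @export
qc_normalize_smooth <- function(counts, bins = NULL, min_reads = 300L,
                                n_pcs = 20L, k = 20L) {
  depth <- Matrix::rowSums(counts)
  keep <- depth >= min_reads
  if (sum(keep) < k + 1L) {
    abort(sprintf("only %d bins pass QC; smoothing over %d neighbours impossible.",
                  sum(keep), k))
  }
  counts <- counts[keep, , drop = FALSE]
  depth <- depth[keep]

  norm <- as.matrix(counts) * (mean(depth) / depth)
  lg <- log2(norm + 1)

  centered <- sweep(lg, 2, colMeans(lg))
  n_pcs <- min(n_pcs, nrow(lg) - 1L, ncol(lg))
  pca <- prcomp(centered, center = FALSE, rank. = n_pcs)
  pcs <- pca$x

  nn <- knn_index(pcs, k, include_self = TRUE)
  smoothed <- matrix(0, nrow(lg), ncol(lg), dimnames = dimnames(lg))
  for (j in seq_len(k)) smoothed <- smoothed + lg[nn[, j], , drop = FALSE]
  smoothed <- smoothed / k

  if (!is.null(bins)) bins <- filter(bins, .data$bin_id %in% rownames(lg))
  structure(list(smoothed = smoothed, normalized = lg, pcs = pcs,
                 bins = bins, depth = depth),
            class = "spatial_smooth")
}

#' @exportS3Method base::print
print.spatial_smooth <- function(x, ...) {
  cat("<spatial_smooth> ", nrow(x$smoothed), " bins x ", ncol(x$smoothed),
      " genes, ", ncol(x$pcs), " PCs\n", sep = "")
  invisible(x)
}

# z-score a vector; a constant vector gets z = 0 everywhere (avoids spurious
# threshold calls on flat fields), optionally capped for visualisation.
gene_z <- function(v, cap = NULL) {
  s <- sd(v)
  z <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  if (!is.null(cap)) z <- pmin(cap, pmax(-cap, z))
  z
}

#' Call tumor bins by smoothed marker expression
#'
#' Z-scores the PC-smoothed expression of a marker gene (Axin2 by default)
#' over all QC-passing bins and calls bins with `z >= min_z` (inclusive) as
#' tumor bins. A constant marker yields z = 0 everywhere and hence no calls.
#'
#' @param smooth A `"spatial_smooth"` from [qc_normalize_smooth()] (needs
#'   `bins` coordinates).
#' @param gene Marker gene (default `"Axin2"`).
#' @param min_z Call threshold (default 1).
#' @return Tibble `bin_id`, `x`, `y`, `z`, `tumor_cell`.
#' @export
call_tumor_bins <- function(smooth, gene = "Axin2", min_z = 1) {
  stopifnot(inherits(smooth, "spatial_smooth"))
  if (!gene %in% colnames(smooth$smoothed)) {
    abort(sprintf("gene '%s' not present.", gene))
  }
  if (is.null(smooth$bins)) abort("bin coordinates required (pass `bins` to qc_normalize_smooth).")
  z <- unname(gene_z(smooth$smoothed[, gene]))
  tibble(bin_id = rownames(smooth$smoothed)) |>
    inner_join(smooth$bins, by = "bin_id") |>
    mutate(z = z, tumor_cell = z >= min_z) |>
    select("bin_id", "x", "y", "z", "tumor_cell")
}

#' Segment called tumor bins into individual tumors
#'
#' Builds the symmetrised k-nearest-neighbour graph (k = 5) over the spatial
#' coordinates of tumor-called bins only and partitions it with seeded
#' Louvain community detection; each community is one tumor. With at most
#' `k + 1` called bins the graph is complete and a single tumor is returned.
#'
#' @param calls Output of [call_tumor_bins()] (rows with
#'   `tumor_cell == TRUE` are used), or any tibble `bin_id`, `x`, `y`.
#' @param k Neighbours in the spatial graph (default 5).
#' @param resolution Louvain resolution (default 0.1, at which a single
#'   solid disc of bins stays one community).
#' @param seed RNG seed for Louvain (default 1).
#' @return Tibble `bin_id`, `x`, `y`, `tumor_id`, tumors numbered by
#'   decreasing size.
#' @export
segment_tumors <- function(calls, k = 5L, resolution = 0.1, seed = 1L) {
  if ("tumor_cell" %in% names(calls)) calls <- filter(calls, .data$tumor_cell)
  stopifnot(all(c("bin_id", "x", "y") %in% names(calls)))
  n <- nrow(calls)
  if (n < 1) abort("no tumor bins to segment.")
  if (n <= k + 1L) {
    member <- rep(1L, n)
  } else {
    nn <- knn_index(as.matrix(calls[, c("x", "y")]), k)
    el <- cbind(rep(seq_len(n), k), as.vector(nn))
    g <- simplify(graph_from_edgelist(el, directed = FALSE))
    set.seed(seed)
    member <- as.integer(membership(cluster_louvain(g, resolution = resolution)))
  }
  sizes <- table(member)
  rank <- rank(-as.vector(sizes), ties.method = "first")
  relabel <- setNames(rank, names(sizes))
  calls |>
    mutate(tumor_id = sprintf("tumor_%02d", relabel[as.character(member)])) |>
    select("bin_id", "x", "y", "tumor_id") |>
    arrange(.data$tumor_id, .data$bin_id)
}

#' Score tumors for program expression
#'
#' Pseudobulks raw counts over each tumor's member bins and scores the
#' pseudobulks for a gene program with the background-matched deviation
#' score ([deviation_scores()], treating tumors as cells and using binary
#' program membership with expression-binned background genes). Tumors with
#' a score above `high_threshold` are flagged as high-program (high AP-1).
#'
#' @param segments Output of [segment_tumors()].
#' @param counts Raw bin x gene counts (all QC bins; rows are subset to the
#'   segmented bins).
#' @param program_genes Character vector of program gene ids; must overlap
#'   the count matrix columns.
#' @param n_background,n_bins,seed Background-set parameters (see
#'   [sample_background_sets()]).
#' @param high_threshold High-program threshold on the score (default 1.5,
#'   strict; an alternative stricter contrast can be obtained with 3).
#' @return Tibble `tumor_id`, `n_bins`, `total_reads`, `score`, `high_ap1`.
#' @export
score_tumors <- function(segments, counts, program_genes,
                         n_background = 250L, n_bins = 20L, seed = 1L,
                         high_threshold = 1.5) {
  genes <- intersect(program_genes, colnames(counts))
  if (length(genes) == 0) abort("empty gene overlap: no program gene is present in the counts.")
  found <- intersect(segments$bin_id, rownames(counts))
  if (length(found) < nrow(segments)) {
    warn("some segmented bins are absent from the count matrix.")
  }
  seg <- filter(segments, .data$bin_id %in% found)
  sub <- counts[seg$bin_id, , drop = FALSE]
  pseudo <- rowsum(as.matrix(sub), seg$tumor_id)
  pseudo <- Matrix(pseudo, sparse = TRUE)

  ann <- matrix(0, ncol(pseudo), 1,
                dimnames = list(colnames(pseudo), "program"))
  ann[genes, 1] <- 1
  scores <- deviation_scores(pseudo, ann, n_background = n_background,
                             n_bins = n_bins, seed = seed)
  seg |>
    count(.data$tumor_id, name = "n_bins") |>
    left_join(tibble(tumor_id = scores$cell, score = scores$program),
              by = "tumor_id") |>
    mutate(total_reads = as.vector(Matrix::rowSums(pseudo))[
             match(.data$tumor_id, rownames(pseudo))],
           high_ap1 = .data$score > high_threshold) |>
    select("tumor_id", "n_bins", "total_reads", "score", "high_ap1")
}
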