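# Exact Euclidean k-nearest neighbours, chunked so the full distance matrix
# is never held for large n. Ties are broken by point index (deterministic).
knn_index <- function(x, k, include_self = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  need <- if (include_self) k else k + 1L
  if (need > n) abort("`k` too large for the number of points.")
  sq <- rowSums(x^2)
  out <- matrix(NA_integer_, n, k)
  chunk <- max(1L, floor(4e6 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    d2 <- sweep(-2 * x[rows, , drop = FALSE] %*% t(x), 2, sq, "+")
    for (ii in seq_along(rows)) {
      i <- rows[ii]
      ord <- order(d2[ii, ], seq_len(n))
      if (!include_self) ord <- ord[ord != i]
      out[i, ] <- ord[seq_len(k)]
    }
  }
  out
}

#' k-NN condition enrichment in a latent embedding
#'
#' For each cell, finds its `k` Euclidean nearest neighbours in the embedding
#' (self excluded, distance ties broken by cell index) and compares the
#' observed fraction of each condition among the neighbours to the expected
#' fraction under random assignment, which is simply each condition's global
#' share of cells. Enrichment is observed minus expected, so it sums to zero
#' across conditions for every cell and is bounded in \[-1, 1\].
#'
#' @param embedding Tibble with a `cell` column plus numeric dimensions
#'   (topics or PCs), or a numeric matrix with cell rownames.
#' @param cells Tibble with columns `cell` and `condition` (or a named
#'   character vector of conditions).
#' @param k Neighbourhood size (default 100).
#' @return Tibble `cell`, `own_condition`, `condition`, `observed`,
#'   `expected`, `enrichment`, one row per cell x condition.
#' @examples
#' emb <- tibble::tibble(cell = sprintf("c%d", 1:20),
#'                       d1 = c(rnorm(10), rnorm(10, 10)), d2 = rnorm(20))
#' lab <- tibble::tibble(cell = emb$cell,
#'                       condition = rep(c("a", "b"), each = 10))
#' knn_condition_enrichment(emb, lab, k = 5)
#' @export
knn_condition_enrichment <- function(embedding, cells, k = 100L) {
  if (is.data.frame(embedding)) {
    stopifnot("cell" %in% names(embedding))
    ids <- embedding$cell
    x <- as.matrix(embedding[setdiff(names(embedding), "cell")])
  } else {
    x <- as.matrix(embedding)
    ids <- rownames(x) %||% sprintf("cell_%05d", seq_len(nrow(x)))
  }
  if (ncol(x) < 2) abort("embedding needs at least 2 dimensions.")
  if (!all(is.finite(x))) abort("embedding must be finite.")
  if (is.data.frame(cells)) {
    cond <- setNames(as.character(cells$condition), cells$cell)[ids]
  } else {
    cond <- as.character(cells[ids])
  }
  if (anyNA(cond)) abort("every embedded cell needs a condition label.")
  if (k >= length(ids)) abort("`k` must be smaller than the number of cells.")

  nn <- knn_index(x, k)
  levels <- sort(unique(cond))
  cond_f <- factor(cond, levels = levels)
  expected <- as.vector(table(cond_f)) / length(cond)

  # counts of each condition among the k neighbours
  neigh_cond <- matrix(as.integer(cond_f)[nn], nrow(nn), k)
  obs <- vapply(seq_along(levels), function(l) {
    rowSums(neigh_cond == l) / k
  }, numeric(nrow(nn)))

  list_rbind(map(seq_along(levels), function(l) {
    tibble(cell = ids, own_condition = cond, condition = levels[l],
           observed = obs[, l], expected = expected[l],
           enrichment = obs[, l] - expected[l])
  })) |>
    arrange(.data$cell, .data$condition)
}
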