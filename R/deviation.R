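#' Expected counts under the depth x feature-abundance null
#'
#' The null expectation for cell i and feature f is
#' `e_if = depth_i * total_f / grand_total`, i.e. reads fall into features
#' proportionally to overall feature abundance regardless of cell identity.
#' The expectation is held as its two factors and never materialised dense.
#'
#' @param counts Sparse (or dense) cell x feature count matrix.
#' @return An object of class `"expected_counts"` with elements `depth`
#'   (per-cell totals), `feature_totals` and `grand_total`.
#' @examples
#' m <- matrix(1, 4, 5)
#' e <- expected_counts(m)
#' e$depth
#' @export
expected_counts <- function(counts) {
  depth <- Matrix::rowSums(counts)
  totals <- Matrix::colSums(counts)
  grand <- sum(depth)
  if (grand == 0) abort("grand total of counts is zero.")
  structure(list(depth = depth, feature_totals = totals, grand_total = grand),
            class = "expected_counts")
}

# cells x families matrix of expected weighted counts sum_f w_f e_if for a
# features x families weight matrix W.
expected_weighted <- function(expected, w) {
  tw <- as.vector(Matrix::crossprod(w, expected$feature_totals))
  outer(expected$depth, tw) / expected$grand_total
}

#' Sample abundance-matched background feature sets
#'
#' Ranks features by mean count, splits them into `n_bins` equal-size bins,
#' and draws `n_background` background features (with replacement, excluding
#' the feature itself) from each feature's bin. Matching on mean abundance
#' removes the depth/abundance component of deviation scores; users with
#' sequence-aware bins (e.g. GC-matched) can supply `bins` directly.
#'
#' @param counts Cell x feature count matrix.
#' @param n_bins Number of abundance bins (default 20).
#' @param n_background Background features per feature (default 250).
#' @param seed RNG seed for the draws.
#' @param bins Optional precomputed integer bin assignment per feature.
#' @return Integer matrix (features x n_background) of background feature
#'   indices, with feature names as rownames.
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(40, 5), 4, 10,
#'             dimnames = list(NULL, paste0("f", 1:10)))
#' b <- sample_background_sets(m, n_bins = 2, n_background = 5, seed = 1)
#' dim(b)
#' @export
sample_background_sets <- function(counts, n_bins = 20L, n_background = 250L,
                                   seed = 1L, bins = NULL) {
  stopifnot(n_bins >= 1, n_background >= 1)
  m <- ncol(counts)
  if (is.null(bins)) {
    mean_count <- Matrix::colSums(counts) / nrow(counts)
    # equal-size bins by abundance rank; ties broken by feature index
    bins <- as.integer(ceiling(rank(mean_count, ties.method = "first") *
                                 n_bins / m))
  }
  stopifnot(length(bins) == m)
  set.seed(seed)
  out <- matrix(NA_integer_, m, n_background)
  for (b in unique(bins)) {
    members <- which(bins == b)
    for (f in members) {
      pool <- if (length(members) > 1) members[members != f] else members
      out[f, ] <- pool[sample.int(length(pool), n_background, replace = TRUE)]
    }
  }
  rownames(out) <- colnames(counts)
  out
}

#' Background-normalised deviation scores
#'
#' For each feature set (motif family or gene program) with weights `w` over
#' features, the raw deviation of cell i is
#' `Y_i = (sum_f w_f x_if - sum_f w_f e_if) / sum_f w_f e_if`,
#' the relative excess of observed weighted counts over the
#' depth-and-abundance expectation. Each of the `n_background` replicates
#' recomputes `Y` after substituting every weighted feature by its matched
#' background feature (keeping the weight), and the score is the z-score of
#' the observed `Y` against the background replicates:
#' `z_i = (Y_i - mean_b Y_i^(b)) / sd_b Y_i^(b)`.
#' Binary membership annotations are the special case `w` in \{0, 1\}.
#'
#' When the background standard deviation is zero the score is defined as 0
#' if the raw deviation equals the background mean (the all-null case) and is
#' otherwise emitted as `NA` with a warning.
#'
#' @param counts Sparse cell x feature count matrix with dimnames.
#' @param annotation Feature x family weight matrix (binary membership or
#'   probability weights); column names are the family names.
#' @param backgrounds Optional background index matrix from
#'   [sample_background_sets()]; computed from `counts` when `NULL`.
#' @param expected Optional [expected_counts()] object.
#' @param n_background,n_bins,seed Passed to [sample_background_sets()] when
#'   `backgrounds` is `NULL`.
#' @return A tibble with a `cell` column and one numeric score column per
#'   family.
#' @examples
#' set.seed(1)
#' m <- matrix(rpois(60, 5), 3, 20,
#'             dimnames = list(paste0("c", 1:3), paste0("f", 1:20)))
#' ann <- matrix(0, 20, 1, dimnames = list(colnames(m), "fam"))
#' ann[1:3, 1] <- 1
#' deviation_scores(m, ann, n_background = 10, n_bins = 2, seed = 1)
#' @export
deviation_scores <- function(counts, annotation, backgrounds = NULL,
                             expected = NULL, n_background = 250L,
                             n_bins = 20L, seed = 1L) {
  stopifnot(!is.null(colnames(counts)))
  if (is.null(rownames(annotation))) {
    stopifnot(nrow(annotation) == ncol(counts))
  } else {
    stopifnot(all(rownames(annotation) == colnames(counts)))
  }
  w <- Matrix(as.matrix(annotation) + 0, sparse = TRUE)  # force numeric
  fams <- colnames(annotation) %||% sprintf("family_%02d", seq_len(ncol(w)))
  if (any(Matrix::colSums(w != 0) == 0)) {
    abort("every family must annotate at least one feature.")
  }
  expected <- expected %||% expected_counts(counts)
  backgrounds <- backgrounds %||%
    sample_background_sets(counts, n_bins = n_bins,
                           n_background = n_background, seed = seed)
  n_bg <- ncol(backgrounds)

  raw_dev <- function(wmat) {
    e <- expected_weighted(expected, wmat)
    obs <- as.matrix(counts %*% wmat)
    (obs - e) / e
  }
  y <- raw_dev(w)

  # running moments over background replicates
  trip <- summary(w)  # i = feature, j = family, x = weight
  sum_y <- matrix(0, nrow(y), ncol(y))
  sum_y2 <- matrix(0, nrow(y), ncol(y))
  for (b in seq_len(n_bg)) {
    wb <- sparseMatrix(i = backgrounds[trip$i, b], j = trip$j, x = trip$x,
                       dims = dim(w))
    yb <- raw_dev(wb)
    sum_y <- sum_y + yb
    sum_y2 <- sum_y2 + yb * yb
  }
  mean_b <- sum_y / n_bg
  var_b <- pmax((sum_y2 - sum_y^2 / n_bg) / (n_bg - 1), 0)
  sd_b <- sqrt(var_b)

  z <- (y - mean_b) / sd_b
  degenerate <- sd_b == 0
  z[degenerate & (y - mean_b == 0)] <- 0
  undefined <- degenerate & (y - mean_b != 0)
  if (any(undefined)) {
    z[undefined] <- NA_real_
    warn(sprintf("%d deviation scores undefined (zero background variance).",
                 sum(undefined)))
  }
  colnames(z) <- fams
  bind_cols(tibble(cell = rownames(counts) %||%
                     sprintf("cell_%05d", seq_len(nrow(z)))),
            as_tibble(z))
}

# wide scores tibble -> matrix
scores_matrix <- function(scores) {
  stopifnot(is.data.frame(scores), "cell" %in% names(scores))
  m <- as.matrix(scores[setdiff(names(scores), "cell")])
  rownames(m) <- scores$cell
  m
}

#' Bag motifs into families by similarity and variability
#'
#' Greedy leader clustering: motifs are visited in decreasing variability
#' (ties by name); an unmerged motif becomes a family leader and all still
#' unmerged motifs with similarity q-value below `q_cutoff` to that leader
#' join its family. The leader's annotation set then represents the family.
#'
#' @param q_values Symmetric motif x motif q-value matrix with dimnames.
#' @param variability Named numeric vector of per-motif variability (e.g.
#'   variance of deviation scores across cells).
#' @param q_cutoff Merge threshold (default 0.05).
#' @return Tibble `motif`, `family` (leader motif), `leader` (logical).
#' @examples
#' q <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' bag_motif_families(q, c(A = 2, B = 1))
#' @export
bag_motif_families <- function(q_values, variability, q_cutoff = 0.05) {
  motifs <- names(variability)
  stopifnot(!is.null(motifs), all(motifs %in% rownames(q_values)))
  ord <- motifs[order(-variability, motifs)]
  family <- setNames(rep(NA_character_, length(motifs)), ord)
  for (m in ord) {
    if (!is.na(family[m])) next
    family[m] <- m
    candidates <- ord[is.na(family[ord])]
    merge_in <- candidates[q_values[m, candidates] < q_cutoff]
    family[merge_in] <- m
  }
  assigned <- unname(family[ord])
  tibble(motif = ord, family = assigned, leader = ord == assigned)
}

#' Select the top program genes by topic weight
#'
#' @param topic_weights Gene x topic weight matrix with dimnames, or a tibble
#'   with columns `gene` and `weight`.
#' @param topic Topic (program) name or index; ignored for the tibble form.
#' @param k Number of genes (default 150).
#' @return Character vector of gene ids, highest weight first; ties at the
#'   cutoff are broken by gene id.
#' @examples
#' w <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("g1", "g2", "g3"), "p1"))
#' select_program_genes(w, "p1", k = 2)
#' @export
select_program_genes <- function(topic_weights, topic = 1L, k = 150L) {
  if (is.data.frame(topic_weights)) {
    genes <- topic_weights$gene
    weights <- topic_weights$weight
  } else {
    genes <- rownames(topic_weights)
    weights <- topic_weights[, topic]
  }
  stopifnot(!is.null(genes))
  ord <- order(-weights, genes)
  genes[ord][seq_len(min(k, length(genes)))]
}
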