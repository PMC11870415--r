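#' Clonal-variance permutation test for heritability of single-cell scores
#'
#' For each feature, the observed clonal variance is the median across clones
#' of the within-clone standard deviation of single-cell scores, squared.
#' Cell-to-clone assignments are then permuted uniformly over all
#' clone-assigned cells (preserving clone sizes) `n_perm` times and the
#' statistic recomputed; the z-score of the observed statistic against the
#' permutation moments gives a two-sided normal p-value,
#' `p = 2 * pnorm(-|Z|)`, adjusted across features by Benjamini-Hochberg.
#' Heritable features sit *below* the null (cells of a clone resemble each
#' other), so heritability shows as negative Z.
#'
#' Permutation is global across all clone-assigned cells, so consistent
#' sample-level differences (e.g. anatomical position) register as clonal
#' signal; `stratify_by_sample = TRUE` restricts shuffling to within-sample
#' and removes that component.
#'
#' @param scores Wide scores tibble from [deviation_scores()].
#' @param clones A `"clone_assignment"` or a tibble with columns `cell`,
#'   `clone_id` (and `sample` when stratifying).
#' @param n_perm Number of permutations (default 1000; minimum 100).
#' @param seed RNG seed; fixed seed reproduces Z exactly.
#' @param stratify_by_sample Permute within samples only (default FALSE).
#' @param return_null Keep the full matrix of shuffled statistics
#'   (`n_perm` x features) in the result as `null_statistics`, e.g. to
#'   inspect the permutation null directly (default FALSE).
#' @return An object of class `"clonal_variance_test"`; `tidy()` returns the
#'   per-feature table (`feature`, `observed_clonal_variance`,
#'   `mean_shuffled_clonal_variance`, `stdev_shuffled_clonal_variance`, `z`,
#'   `p_value`, `fdr`, `degenerate`), `glance()` a one-row summary.
#'   Constant features are flagged `degenerate` and excluded from the FDR.
#' @examples
#' set.seed(1)
#' sc <- tibble::tibble(cell = sprintf("c%02d", 1:40),
#'                      f1 = rnorm(40), f2 = rep(rnorm(8), each = 5))
#' cl <- tibble::tibble(cell = sc$cell,
#'                      clone_id = rep(sprintf("cl%d", 1:8), each = 5))
#' tidy(clonal_variance_test(sc, cl, n_perm = 100, seed = 1))
#' @export
clonal_variance_test <- function(scores, clones, n_perm = 1000L, seed = 1L,
                                 stratify_by_sample = FALSE,
                                 return_null = FALSE) {
  if (inherits(clones, "clone_assignment")) clones <- clones$cell_clones
  stopifnot(all(c("cell", "clone_id") %in% names(clones)))
  if (n_perm < 100) abort("`n_perm` must be at least 100.")

  joined <- inner_join(scores, select(clones, "cell", "clone_id",
                                      any_of("sample")),
                       by = "cell")
  if (nrow(joined) == 0) abort("no cells shared between `scores` and `clones`.")
  feats <- setdiff(names(scores), "cell")
  s <- as.matrix(joined[feats])
  clone <- factor(joined$clone_id)
  sizes <- tabulate(clone)
  if (any(sizes < 2)) abort("every clone must contain at least 2 cells.")

  stat <- function(m) {
    sums <- rowsum(m, clone)        # rows in factor-level order,
    sq <- rowsum(m * m, clone)      # matching tabulate(clone)
    v <- pmax((sq - sums^2 / sizes) / (sizes - 1), 0)
    apply(sqrt(v), 2, median)^2
  }

  observed <- stat(s)

  set.seed(seed)
  n <- nrow(s)
  if (stratify_by_sample) {
    stopifnot("sample" %in% names(joined))
    strata <- split(seq_len(n), joined$sample)
  }
  sum_t <- numeric(length(feats))
  sum_t2 <- numeric(length(feats))
  null_stats <- if (return_null) {
    matrix(NA_real_, n_perm, length(feats), dimnames = list(NULL, feats))
  }
  for (b in seq_len(n_perm)) {
    perm <- if (stratify_by_sample) {
      idx <- integer(n)
      for (g in strata) idx[g] <- g[sample.int(length(g))]
      idx
    } else {
      sample.int(n)
    }
    tb <- stat(s[perm, , drop = FALSE])
    if (return_null) null_stats[b, ] <- tb
    sum_t <- sum_t + tb
    sum_t2 <- sum_t2 + tb * tb
  }
  mean_null <- sum_t / n_perm
  sd_null <- sqrt(pmax(0, (sum_t2 - sum_t^2 / n_perm) / (n_perm - 1)))

  degenerate <- sd_null == 0
  z <- (observed - mean_null) / sd_null
  z[degenerate] <- NA_real_
  p <- 2 * pnorm(-abs(z))
  fdr <- rep(NA_real_, length(p))
  fdr[!degenerate] <- p.adjust(p[!degenerate], method = "BH")
  if (any(degenerate)) {
    warn(sprintf("%d constant feature(s) excluded from the FDR.",
                 sum(degenerate)))
  }

  result <- tibble(
    feature = feats,
    observed_clonal_variance = unname(observed),
    mean_shuffled_clonal_variance = unname(mean_null),
    stdev_shuffled_clonal_variance = unname(sd_null),
    z = unname(z), p_value = unname(p), fdr = fdr,
    degenerate = unname(degenerate)
  )
  structure(list(result = result, n_perm = n_perm, seed = seed,
                 n_clones = nlevels(clone), n_cells = n,
                 stratified = stratify_by_sample,
                 null_statistics = null_stats),
            class = "clonal_variance_test")
}

#' @exportS3Method base::print
print.clonal_variance_test <- function(x, ...) {
  cat("<clonal_variance_test> ", nrow(x$result), " features, ",
      x$n_clones, " clones, ", x$n_cells, " cells, ",
      x$n_perm, " permutations", if (x$stratified) " (within-sample)", "\n",
      sep = "")
  print(head(arrange(x$result, .data$p_value), 10))
  invisible(x)
}

#' @rdname clonal_variance_test
#' @param x A `clonal_variance_test`.
#' @param ... Unused.
#' @export
tidy.clonal_variance_test <- function(x, ...) x$result

#' @rdname clonal_variance_test
#' @export
glance.clonal_variance_test <- function(x, ...) {
  tibble(n_features = nrow(x$result), n_clones = x$n_clones,
         n_cells = x$n_cells, n_perm = x$n_perm,
         n_heritable = sum(x$result$fdr < 0.05 & x$result$z < 0, na.rm = TRUE))
}

#' Per-clone score summaries
#'
#' The median and standard deviation of single-cell scores per clone and
#' feature, with clone size and sample/condition labels: the unit of analysis
#' for between-condition clone comparisons.
#'
#' @param scores Wide scores tibble.
#' @param clones A `"clone_assignment"` or tibble `cell`, `clone_id`.
#' @param cells Optional tibble `cell`, `sample`, `condition` to label clones.
#' @return Long tibble `clone_id`, `sample`, `condition`, `size`, `feature`,
#'   `median`, `sd`.
#' @export
clone_summary <- function(scores, clones, cells = NULL) {
  if (inherits(clones, "clone_assignment")) clones <- clones$cell_clones
  joined <- inner_join(scores, select(clones, "cell", "clone_id"), by = "cell")
  if (!is.null(cells)) {
    joined <- left_join(joined,
                        select(cells, "cell", any_of(c("sample", "condition"))),
                        by = "cell")
  }
  feats <- setdiff(names(scores), "cell")
  joined |>
    pivot_longer(all_of(feats), names_to = "feature", values_to = "score") |>
    group_by(.data$clone_id, across(any_of(c("sample", "condition"))),
             .data$feature) |>
    summarise(size = n(), median = median(.data$score, na.rm = TRUE),
              sd = sd(.data$score, na.rm = TRUE), .groups = "drop")
}

#' Compare clone-level score distributions between conditions
#'
#' Between two arms: a KS test on the within-clone standard deviations, the
#' difference of clone-median-of-medians and of median within-clone SDs
#' (condition minus control), and each arm's fraction of high clones (clone
#' median score above `high_threshold`).
#'
#' @param summary Output of [clone_summary()] (needs a `condition` column).
#' @param feature Feature to compare.
#' @param condition,control Arm labels (condition minus control).
#' @param high_threshold Clone-median threshold for a "high" clone
#'   (default 1.25).
#' @return One-row tibble with the statistics above.
#' @export
compare_clone_distributions <- function(summary, feature, condition, control,
                                        high_threshold = 1.25) {
  stopifnot("condition" %in% names(summary))
  a <- filter(summary, .data$feature == !!feature,
              .data$condition == !!condition)
  b <- filter(summary, .data$feature == !!feature,
              .data$condition == !!control)
  if (nrow(a) < 3 || nrow(b) < 3) {
    warn("fewer than 3 clones in an arm; comparisons are unstable.")
  }
  ks <- suppressWarnings(ks.test(a$sd, b$sd))
  tibble(
    feature = feature, condition = condition, control = control,
    n_clones_condition = nrow(a), n_clones_control = nrow(b),
    ks_p_sd = ks$p.value,
    delta_median = median(a$median) - median(b$median),
    delta_sd = median(a$sd) - median(b$sd),
    high_fraction_condition = mean(a$median > high_threshold),
    high_fraction_control = mean(b$median > high_threshold)
  )
}

#' Correlate clone-level motif and program scores
#'
#' Averages each feature over the cells of each clone in both score sets and
#' computes the Pearson correlation of the clone means for every
#' (motif family, program) pair. Pairs with a zero-variance vector are
#' returned as `NA`.
#'
#' @param motif_scores,program_scores Wide scores tibbles sharing cells.
#' @param clones A `"clone_assignment"` or tibble `cell`, `clone_id`.
#' @return Tibble `motif_family`, `program`, `r`, `n_clones`.
#' @export
correlate_clone_features <- function(motif_scores, program_scores, clones) {
  if (inherits(clones, "clone_assignment")) clones <- clones$cell_clones
  clone_means <- function(scores) {
    joined <- inner_join(scores, select(clones, "cell", "clone_id"),
                         by = "cell")
    m <- as.matrix(joined[setdiff(names(scores), "cell")])
    g <- factor(joined$clone_id)
    rowsum(m, g) / as.vector(table(g))
  }
  a <- clone_means(motif_scores)
  b <- clone_means(program_scores)
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < 3) abort("need at least 3 shared clones.")
  a <- a[common, , drop = FALSE]
  b <- b[common, , drop = FALSE]
  r <- suppressWarnings(cor(a, b))  # NA for zero-variance vectors
  as_tibble(r, rownames = "motif_family") |>
    pivot_longer(-"motif_family", names_to = "program", values_to = "r") |>
    mutate(n_clones = length(common))
}
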