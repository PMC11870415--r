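#' Plot the clonal-variance test results
#'
#' Features ranked by Z, coloured by FDR significance; heritable features
#' (low within-clone variance) fall below zero.
#'
#' @param object A [clonal_variance_test()].
#' @param fdr_cutoff Significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonal_variance_test <- function(object, fdr_cutoff = 0.05, ...) {
  d <- tidy(object) |>
    filter(!.data$degenerate) |>
    arrange(.data$z) |>
    mutate(rank = row_number(),
           significant = .data$fdr < fdr_cutoff)
  ggplot(d, aes(x = .data$rank, y = .data$z, colour = .data$significant)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_point(size = 1) +
    scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    labs(x = "feature rank", y = "clonal-variance Z",
         colour = sprintf("FDR < %g", fdr_cutoff)) +
    theme_minimal()
}

#' Heatmap-style view of per-sample score changes
#'
#' Tiles the change vs control per family and sample; samples flagged as
#' under the cell-count threshold are dropped, as in heatmap outputs.
#'
#' @param object A [condition_summary()].
#' @param families Optional family subset.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condition_summary <- function(object, families = NULL, ...) {
  d <- object$sample_means |> filter(.data$included)
  if (!is.null(families)) d <- filter(d, .data$family %in% families)
  ggplot(d, aes(x = .data$sample, y = .data$family, fill = .data$change)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    facet_grid(cols = vars(.data$condition), scales = "free_x",
               space = "free_x") +
    labs(x = NULL, y = NULL, fill = "change\nvs control") +
    theme_minimal()
}

#' Own-condition k-NN enrichment per condition
#'
#' Boxplots of each cell's enrichment for its own condition, a compact view
#' of how epigenomically separated the conditions are.
#'
#' @param enrichment Output of [knn_condition_enrichment()].
#' @return A ggplot.
#' @export
plot_knn_enrichment <- function(enrichment) {
  d <- filter(enrichment, .data$condition == .data$own_condition)
  ggplot(d, aes(x = .data$own_condition, y = .data$enrichment,
                fill = .data$own_condition)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    labs(x = NULL, y = "own-condition enrichment\n(observed - expected)") +
    theme_minimal()
}

#' Co-binding score matrix
#'
#' @param cobinding Output of [normalize_cobinding()].
#' @return A ggplot tile map of normalised co-binding scores.
#' @export
plot_cobinding <- function(cobinding) {
  ggplot(cobinding, aes(x = .data$family_a, y = .data$family_b,
                        fill = .data$cobinding_score)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "co-binding") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Spatial tumor map
#'
#' Called bins on the spatial grid coloured by tumor, optionally annotated
#' with per-tumor program scores.
#'
#' @param segments Output of [segment_tumors()].
#' @param scores Optional output of [score_tumors()]; high-program tumors
#'   are outlined in the label.
#' @return A ggplot.
#' @export
plot_spatial_tumors <- function(segments, scores = NULL) {
  d <- segments
  if (!is.null(scores)) {
    d <- left_join(d, select(scores, "tumor_id", "score", "high_ap1"),
                   by = "tumor_id") |>
      mutate(label = if_else(.data$high_ap1,
                             paste0(.data$tumor_id, "*"), .data$tumor_id))
  } else {
    d$label <- d$tumor_id
  }
  ggplot(d, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_point(size = 1.2) +
    coord_fixed() +
    labs(x = "x (bins)", y = "y (bins)", colour = "tumor") +
    theme_minimal()
}
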