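#' Simulate a clone-structured single-cell multiome experiment
#'
#' Generates latent per-cell family scores with a planted intraclass
#' correlation (clone effects), condition mean-shifts and a high-memory clone
#' subpopulation, then draws sparse cell-by-peak and cell-by-gene count
#' matrices whose rates are tied to the latent scores through the peak-family
#' annotation and the topic (program) weights.
#'
#' The latent model per cell i and family f is
#' `s_if = clone_effect + condition_shift + cell_noise`, with
#' `Var(clone_effect) = icc_f` and `Var(cell_noise) = 1 - icc_f` so the total
#' latent variance is 1. A `high_memory_fraction` of exposed-condition clones
#' receive an extra `delta_high` on the designated memory families. Counts
#' are drawn per cell as a multinomial of the sampled log-normal depth over
#' feature rates (Poisson given rates, conditioned on the cell total), so
#' per-cell count totals equal the sampled depths exactly.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"multiome_sim"`:
#' \describe{
#'   \item{cells}{tibble: `cell`, `sample`, `condition`, `clone`,
#'     `high_memory`, `depth_atac`, `depth_rna`.}
#'   \item{counts_peaks}{sparse cell x peak counts (dgCMatrix).}
#'   \item{counts_genes}{sparse cell x gene counts.}
#'   \item{peaks}{tibble of peak intervals (`peak_id`, `chrom`, `start`,
#'     `end`; 0-based half-open).}
#'   \item{peak_annotation}{sparse binary peak x family membership.}
#'   \item{topic_weights}{gene x program weight matrix, columns sum to 1.}
#'   \item{family_scores}{matrix of the latent per-cell family scores
#'     (ground truth for tests).}
#'   \item{clone_truth}{tibble: `cell`, `clone`, `sample`, `condition`,
#'     `high_memory`.}
#' }
#' @examples
#' sim <- simulate_multiome(simulation_config(
#'   seed = 1, n_samples = 2, n_cells_per_sample = 50,
#'   n_peaks = 200, n_genes = 100, n_clones_per_sample = 4))
#' dim(sim$counts_peaks)
#' @export
simulate_multiome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(artifact_seed(cfg, 1L))

  samples <- sample_names(cfg)
  sample_condition <- condition_of_samples(cfg)
  fams <- family_names(cfg$n_families)
  n_cells <- cfg$n_samples * cfg$n_cells_per_sample

  # --- clone structure -------------------------------------------------------
  clone_tbl <- list_rbind(map(seq_len(cfg$n_samples), function(s) {
    k <- cfg$n_clones_per_sample
    w <- switch(cfg$clone_size_distribution,
      uniform   = rep(1 / k, k),
      geometric = {
        p <- cfg$clone_size_parameter
        w <- (1 - p)^(seq_len(k) - 1)
        w / sum(w)
      })
    sizes <- as.vector(rmultinom(1, cfg$n_cells_per_sample, w))
    tibble(
      sample = samples[s],
      condition = sample_condition[s],
      clone = sprintf("%s_c%02d", samples[s], seq_len(k)),
      size = sizes
    )
  }))
  exposed <- clone_tbl$condition != cfg$conditions[1]
  clone_tbl$high_memory <- exposed &
    (runif(nrow(clone_tbl)) < cfg$high_memory_fraction)

  cells <- clone_tbl |>
    filter(.data$size > 0) |>
    mutate(cell_list = map2(.data$clone, .data$size, function(cl, sz) rep(cl, sz))) |>
    select(-"size")
  cells <- tibble(
    clone = unlist(cells$cell_list),
    sample = rep(cells$sample, lengths(cells$cell_list)),
    condition = rep(cells$condition, lengths(cells$cell_list)),
    high_memory = rep(cells$high_memory, lengths(cells$cell_list))
  )
  cells$cell <- sprintf("cell_%05d", seq_len(nrow(cells)))

  # --- latent family scores --------------------------------------------------
  clone_ids <- clone_tbl$clone
  clone_idx <- match(cells$clone, clone_ids)
  icc <- cfg$icc_per_family
  clone_eff <- matrix(rnorm(length(clone_ids) * cfg$n_families),
                      length(clone_ids), cfg$n_families)
  clone_eff <- sweep(clone_eff, 2, sqrt(icc), "*")
  # high-memory component: clone-level shift on the memory families
  for (f in cfg$memory_families) {
    clone_eff[clone_tbl$high_memory, f] <- clone_eff[clone_tbl$high_memory, f] +
      cfg$delta_high
  }
  noise <- matrix(rnorm(nrow(cells) * cfg$n_families),
                  nrow(cells), cfg$n_families)
  noise <- sweep(noise, 2, sqrt(1 - icc), "*")
  shift <- outer(cells$condition != cfg$conditions[1],
                 cfg$condition_shift_per_family)
  scores <- clone_eff[clone_idx, , drop = FALSE] + noise + shift
  dimnames(scores) <- list(cells$cell, fams)

  # --- peaks, annotation, peak counts ---------------------------------------
  peak_ids <- sprintf("peak_%05d", seq_len(cfg$n_peaks))
  peaks <- tibble(
    peak_id = peak_ids, chrom = "chr1",
    start = (seq_len(cfg$n_peaks) - 1L) * 1000L,
    end = (seq_len(cfg$n_peaks) - 1L) * 1000L + 500L
  )
  n_annot <- max(1L, round(0.08 * cfg$n_peaks))
  annot_idx <- map(seq_len(cfg$n_families), function(f) {
    sort(sample.int(cfg$n_peaks, n_annot))
  })
  peak_annotation <- sparseMatrix(
    i = unlist(annot_idx),
    j = rep(seq_len(cfg$n_families), lengths(annot_idx)),
    x = 1, dims = c(cfg$n_peaks, cfg$n_families),
    dimnames = list(peak_ids, fams)
  )

  depth_atac <- pmax(1L, round(rlnorm(n_cells, cfg$depth_lognormal["mu"],
                                      cfg$depth_lognormal["sigma"])))
  base_peak <- rnorm(cfg$n_peaks, 0, 0.7)
  # log-rate per cell x peak: base + 0.3 * sum of scores of annotating families
  counts_peaks <- draw_counts(scores, peak_annotation, base_peak, depth_atac,
                              effect = 0.3)
  dimnames(counts_peaks) <- list(cells$cell, peak_ids)

  # --- genes, programs, gene counts -----------------------------------------
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))
  g_per <- max(1L, floor(cfg$n_genes / (cfg$n_families + 1L)))
  topic_weights <- matrix(0.01 / cfg$n_genes, cfg$n_genes, cfg$n_families,
                          dimnames = list(gene_ids, fams))
  prog_members <- map(seq_len(cfg$n_families), function(f) {
    seq.int((f - 1L) * g_per + 1L, f * g_per)
  })
  for (f in seq_len(cfg$n_families)) {
    topic_weights[prog_members[[f]], f] <- 1
  }
  topic_weights <- sweep(topic_weights, 2, colSums(topic_weights), "/")

  gene_annotation <- sparseMatrix(
    i = unlist(prog_members),
    j = rep(seq_len(cfg$n_families), lengths(prog_members)),
    x = 1, dims = c(cfg$n_genes, cfg$n_families),
    dimnames = list(gene_ids, fams)
  )
  depth_rna <- pmax(1L, round(rlnorm(n_cells, cfg$depth_lognormal["mu"],
                                     cfg$depth_lognormal["sigma"])))
  base_gene <- rnorm(cfg$n_genes, 0, 0.7)
  counts_genes <- draw_counts(scores, gene_annotation, base_gene, depth_rna,
                              effect = 0.3)
  dimnames(counts_genes) <- list(cells$cell, gene_ids)

  cells_out <- cells |>
    mutate(depth_atac = as.integer(depth_atac),
           depth_rna = as.integer(depth_rna)) |>
    select("cell", "sample", "condition", "clone", "high_memory",
           "depth_atac", "depth_rna")

  structure(list(
    cells = cells_out,
    counts_peaks = counts_peaks,
    counts_genes = counts_genes,
    peaks = peaks,
    peak_annotation = peak_annotation,
    topic_weights = topic_weights,
    family_scores = scores,
    clone_truth = cells_out |>
      select("cell", "clone", "sample", "condition", "high_memory"),
    config = cfg
  ), class = "multiome_sim")
}

# Multinomial counts per cell over features with log-linear family effects.
draw_counts <- function(scores, annotation, base_log_rate, depths, effect) {
  n_cells <- nrow(scores)
  n_feat <- length(base_log_rate)
  # cells x features log-rate contribution from family scores
  contrib <- effect * (scores %*% t(annotation))
  out <- matrix(0L, n_feat, n_cells)
  for (i in seq_len(n_cells)) {
    rate <- exp(base_log_rate + contrib[i, ])
    out[, i] <- rmultinom(1, depths[i], rate)
  }
  methods::as(t(Matrix(out, sparse = TRUE)), "CsparseMatrix")
}

#' @exportS3Method base::print
print.multiome_sim <- function(x, ...) {
  cat("<multiome_sim> ", nrow(x$cells), " cells, ",
      ncol(x$counts_peaks), " peaks, ", ncol(x$counts_genes), " genes, ",
      length(unique(x$cells$clone)), " clones\n", sep = "")
  invisible(x)
}
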