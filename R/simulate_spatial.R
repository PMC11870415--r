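#' Simulate a binned spatial expression grid with planted tumors
#'
#' Builds a rectangular grid of 16-um bins, places circular tumors without
#' overlap, multiplies the Axin2 probe rate by `axin2_fold_change` inside
#' tumor bins, and elevates AP-1 program gene rates (by
#' `program_fold_change`) in a designated high-AP-1 subset of tumors. Bin
#' counts are multinomial draws of a log-normal bin depth over probe rates;
#' a small fraction of bins is given sub-threshold depth to exercise QC.
#'
#' @param config A [simulation_config()]; see the `spatial` element.
#' @return A list of class `"spatial_sim"`:
#' \describe{
#'   \item{bins}{tibble `bin_id`, `x`, `y`, `total_reads`.}
#'   \item{counts}{sparse bin x probe counts.}
#'   \item{program_genes}{character vector of the planted AP-1 program probes.}
#'   \item{tumors}{tibble `tumor_id`, `x`, `y`, `radius`, `high_ap1`
#'     (planted truth).}
#'   \item{bin_truth}{tibble `bin_id`, `tumor_id` for bins inside tumors.}
#' }
#' @examples
#' sp <- simulate_spatial(simulation_config(
#'   seed = 1, spatial = list(n_x = 30, n_y = 30, n_tumors = 2)))
#' sp$tumors
#' @export
simulate_spatial <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  sp <- cfg$spatial
  set.seed(artifact_seed(cfg, 4L))

  r <- sp$tumor_radius_bins
  grid <- expand_grid(x = seq_len(sp$n_x), y = seq_len(sp$n_y))
  grid$bin_id <- sprintf("bin_%04d_%04d", grid$x, grid$y)
  n_bins <- nrow(grid)

  # --- tumor placement (non-overlapping discs) ------------------------------
  centers <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(centers) < sp$n_tumors) {
    attempts <- attempts + 1L
    if (attempts > 20000L) abort("could not place non-overlapping tumors; shrink radius or count.")
    cand <- c(runif(1, r + 1, sp$n_x - r), runif(1, r + 1, sp$n_y - r))
    if (nrow(centers) == 0 ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= 2 * r + 4) {
      centers <- rbind(centers, cand)
    }
  }
  tumors <- tibble(
    tumor_id = sprintf("tumor_%02d", seq_len(sp$n_tumors)),
    x = centers[, 1], y = centers[, 2], radius = r
  )
  n_high <- round(sp$high_ap1_fraction * sp$n_tumors)
  tumors$high_ap1 <- seq_len(sp$n_tumors) %in%
    sample.int(max(sp$n_tumors, 1L), n_high)

  bin_tumor <- rep(NA_character_, n_bins)
  for (t in seq_len(nrow(tumors))) {
    inside <- (grid$x - tumors$x[t])^2 + (grid$y - tumors$y[t])^2 <= r^2
    bin_tumor[inside] <- tumors$tumor_id[t]
  }

  # --- probes and rates ------------------------------------------------------
  n_prog <- sp$n_program_genes
  program_genes <- sprintf("ap1_prog_%03d", seq_len(n_prog))
  other_genes <- sprintf("probe_%04d", seq_len(max(0L, sp$n_genes - n_prog - 1L)))
  genes <- c("Axin2", program_genes, other_genes)

  base_rate <- rlnorm(length(genes), 0, 0.5)
  names(base_rate) <- genes
  base_rate["Axin2"] <- 2 * mean(base_rate)

  in_tumor <- !is.na(bin_tumor)
  high_bin <- in_tumor & bin_tumor %in% tumors$tumor_id[tumors$high_ap1]

  depth <- pmax(1L, round(rlnorm(n_bins, sp$depth_lognormal["mu"],
                                 sp$depth_lognormal["sigma"])))
  fail <- runif(n_bins) < sp$qc_fail_fraction
  depth[fail] <- sample(50:299, sum(fail), replace = TRUE)

  counts <- matrix(0L, length(genes), n_bins)
  for (i in seq_len(n_bins)) {
    rate <- base_rate
    if (in_tumor[i]) rate["Axin2"] <- rate["Axin2"] * sp$axin2_fold_change
    if (high_bin[i]) rate[program_genes] <- rate[program_genes] * sp$program_fold_change
    counts[, i] <- rmultinom(1, depth[i], rate)
  }
  counts <- methods::as(t(Matrix(counts, sparse = TRUE)), "CsparseMatrix")
  dimnames(counts) <- list(grid$bin_id, genes)

  structure(list(
    bins = tibble(bin_id = grid$bin_id, x = grid$x, y = grid$y,
                  total_reads = as.integer(depth)),
    counts = counts,
    program_genes = program_genes,
    tumors = tumors,
    bin_truth = tibble(bin_id = grid$bin_id, tumor_id = bin_tumor) |>
      filter(!is.na(.data$tumor_id)),
    config = cfg
  ), class = "spatial_sim")
}

#' @exportS3Method base::print
print.spatial_sim <- function(x, ...) {
  cat("<spatial_sim> ", nrow(x$bins), " bins, ", ncol(x$counts), " probes, ",
      nrow(x$tumors), " planted tumors\n", sep = "")
  invisible(x)
}
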