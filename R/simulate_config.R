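#' Configuration for the synthetic clonal-memory data generator
#'
#' Bundles and validates every tunable parameter of the simulators
#' ([simulate_multiome()], [simulate_barcode_reads()], [simulate_footprints()],
#' [simulate_spatial()]). The defaults describe a small two-condition
#' experiment (control vs recovered-from-injury samples) with moderately
#' heritable motif-family scores, a high-memory clone subpopulation on the
#' AP-1-like family, barcoded reads with realistic per-base error, footprint
#' tables with a designated AP-1 reference family, and a 16-um spatial grid
#' with planted Axin2-high tumors.
#'
#' Reproducibility: each simulator derives its own RNG stream from `seed` by a
#' fixed small offset, so regenerating one artifact never perturbs another.
#'
#' @param seed Integer master seed (< 2^31).
#' @param n_samples Number of animals / organoid lines.
#' @param conditions Character vector of condition labels; the first is the
#'   control/reference condition. Samples are assigned round-robin.
#' @param n_cells_per_sample Cells profiled per sample.
#' @param n_peaks,n_genes Number of ATAC peaks and genes.
#' @param n_families Number of motif families / gene programs. The first
#'   family is the AP-1-like memory family and is named `"AP1"`.
#' @param n_clones_per_sample Founder clones per sample.
#' @param clone_size_distribution `"uniform"` (equal expected sizes) or
#'   `"geometric"` (sizes proportional to `(1 - clone_size_parameter)^i`).
#' @param clone_size_parameter Geometric decay parameter in (0, 1).
#' @param icc_per_family Intraclass correlation of clone effects per family,
#'   each in `[0, 1)`; recycled to `n_families`. Latent per-cell family scores
#'   have unit total variance, of which this fraction is between-clone.
#' @param condition_shift_per_family Mean latent-score shift added to cells of
#'   every non-control condition, per family; recycled. Default shifts only
#'   the AP-1-like family by +1.
#' @param memory_families Integer indices of the families carrying the
#'   high-memory effect (default 1, the AP-1-like family).
#' @param high_memory_fraction Probability that an exposed-condition clone is
#'   drawn from the shifted high-memory component.
#' @param delta_high Extra latent shift given to high-memory clones on the
#'   `memory_families`.
#' @param depth_lognormal Named vector `c(mu=, sigma=)` of the log-normal cell
#'   depth distribution (fragments/UMIs per cell).
#' @param n_umis_per_cell Barcode-transcript UMIs captured per cell.
#' @param reads_per_umi Sequencing reads per captured UMI.
#' @param barcode_error_rate Per-base substitution error rate on the 48-bp
#'   barcode; must be < 0.5 for clone recovery to be well posed.
#' @param junk_fraction Fraction of barcode reads replaced by junk (broken
#'   anchor or all-G UMI).
#' @param min_consensus_distance Minimum pairwise Levenshtein distance
#'   enforced between planted clone consensus barcodes (default 9, so that
#'   distance-4 clustering cannot merge planted clones).
#' @param footprint List of footprint-simulator knobs, merged over defaults:
#'   `ap1_rate` (fraction of peaks with an AP-1 memory site), `partner_rate`
#'   (marginal memory rate of each partner family), `cooccurrence` (P(partner
#'   memory | AP-1 memory); scalar or named by family; defaults to
#'   `partner_rate`, i.e. independence), `delta_memory` (range of planted
#'   score gains), `delta_null` (range of non-memory score changes),
#'   `background_site_rate`, `peak_width` (bp), `bin_size` (bp).
#' @param spatial List of spatial-simulator knobs, merged over defaults:
#'   `n_x`, `n_y` (grid size in bins), `bin_size_um`, `n_tumors`,
#'   `tumor_radius_bins`, `axin2_fold_change`, `program_fold_change`,
#'   `high_ap1_fraction` (fraction of tumors with elevated AP-1 program),
#'   `n_program_genes`, `n_genes`, `depth_lognormal`, `qc_fail_fraction`.
#'
#' @return A validated list of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_samples = 2, n_cells_per_sample = 100)
#' cfg$conditions
#' @export
simulation_config <- function(seed = 1L,
                              n_samples = 4L,
                              conditions = c("control", "recovered"),
                              n_cells_per_sample = 400L,
                              n_peaks = 2000L,
                              n_genes = 800L,
                              n_families = 8L,
                              n_clones_per_sample = 15L,
                              clone_size_distribution = c("uniform", "geometric"),
                              clone_size_parameter = 0.15,
                              icc_per_family = 0.3,
                              condition_shift_per_family = c(1, rep(0, n_families - 1)),
                              memory_families = 1L,
                              high_memory_fraction = 0.1,
                              delta_high = 2,
                              depth_lognormal = c(mu = log(2000), sigma = 0.3),
                              n_umis_per_cell = 8L,
                              reads_per_umi = 5L,
                              barcode_error_rate = 0.005,
                              junk_fraction = 0,
                              min_consensus_distance = 9L,
                              footprint = list(),
                              spatial = list()) {
  clone_size_distribution <- match.arg(clone_size_distribution)

  footprint_defaults <- list(
    ap1_rate = 0.2, partner_rate = 0.15, cooccurrence = NULL,
    delta_memory = c(0.25, 0.5), delta_null = c(-0.1, 0.1),
    background_site_rate = 0.3, peak_width = 500L, bin_size = 10L
  )
  spatial_defaults <- list(
    n_x = 48L, n_y = 48L, bin_size_um = 16L, n_tumors = 6L,
    tumor_radius_bins = 4L, axin2_fold_change = 8,
    program_fold_change = 4, high_ap1_fraction = 0.5,
    n_program_genes = 30L, n_genes = 100L,
    depth_lognormal = c(mu = log(1500), sigma = 0.35),
    qc_fail_fraction = 0.02
  )
  footprint <- modifyList(footprint_defaults, footprint)
  spatial <- modifyList(spatial_defaults, spatial)

  cfg <- list(
    seed = as.integer(seed),
    n_samples = as.integer(n_samples),
    conditions = as.character(conditions),
    n_cells_per_sample = as.integer(n_cells_per_sample),
    n_peaks = as.integer(n_peaks),
    n_genes = as.integer(n_genes),
    n_families = as.integer(n_families),
    n_clones_per_sample = as.integer(n_clones_per_sample),
    clone_size_distribution = clone_size_distribution,
    clone_size_parameter = clone_size_parameter,
    icc_per_family = rep_len(icc_per_family, n_families),
    condition_shift_per_family = rep_len(condition_shift_per_family, n_families),
    memory_families = as.integer(memory_families),
    high_memory_fraction = high_memory_fraction,
    delta_high = delta_high,
    depth_lognormal = depth_lognormal,
    n_umis_per_cell = as.integer(n_umis_per_cell),
    reads_per_umi = as.integer(reads_per_umi),
    barcode_error_rate = barcode_error_rate,
    junk_fraction = junk_fraction,
    min_consensus_distance = as.integer(min_consensus_distance),
    footprint = footprint,
    spatial = spatial
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1, is.finite(cfg$seed))
  if (cfg$n_samples < 1) abort("`n_samples` must be >= 1.")
  if (length(cfg$conditions) < 1) abort("at least one condition label is required.")
  if (cfg$n_cells_per_sample < 1) abort("`n_cells_per_sample` must be >= 1 (zero cells rejected).")
  if (cfg$n_clones_per_sample < 1) abort("`n_clones_per_sample` must be >= 1 (zero clones rejected).")
  if (any(cfg$icc_per_family < 0 | cfg$icc_per_family >= 1)) {
    abort("`icc_per_family` values must lie in [0, 1).")
  }
  probs <- c(cfg$high_memory_fraction, cfg$junk_fraction,
             cfg$footprint$ap1_rate, cfg$footprint$partner_rate,
             cfg$spatial$high_ap1_fraction, cfg$spatial$qc_fail_fraction)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1].")
  if (cfg$barcode_error_rate < 0 || cfg$barcode_error_rate >= 0.5) {
    abort("`barcode_error_rate` must lie in [0, 0.5): clone recovery is undefined at >= 0.5.")
  }
  if (any(cfg$memory_families < 1 | cfg$memory_families > cfg$n_families)) {
    abort("`memory_families` indices out of range.")
  }
  if (cfg$clone_size_parameter <= 0 || cfg$clone_size_parameter >= 1) {
    abort("`clone_size_parameter` must lie in (0, 1).")
  }
  cooc <- cfg$footprint$cooccurrence
  if (!is.null(cooc) && any(cooc < 0 | cooc > 1)) abort("`cooccurrence` must lie in [0, 1].")
  invisible(cfg)
}

#' @exportS3Method base::print
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  samples:", x$n_samples, "(", paste(x$conditions, collapse = "/"), ")\n")
  cat("  cells/sample:", x$n_cells_per_sample,
      " clones/sample:", x$n_clones_per_sample, "\n")
  cat("  peaks:", x$n_peaks, " genes:", x$n_genes,
      " families:", x$n_families, "\n")
  cat("  icc:", paste(signif(x$icc_per_family, 3), collapse = " "), "\n")
  cat("  high-memory fraction:", x$high_memory_fraction,
      " delta_high:", x$delta_high, "\n")
  invisible(x)
}

# Family labels used across the simulators; first family is the AP-1-like
# memory family.
family_names <- function(n) {
  base <- c("AP1", "ETS", "RUNX", "SNAI_MESP", "ESRR", "Retinoid",
            "HNF4_PPAR", "FOX")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("family_%02d", seq_len(n - length(base))))
}

# Deterministic per-artifact RNG streams derived from the master seed.
artifact_seed <- function(cfg, offset) {
  (cfg$seed + offset) %% .Machine$integer.max
}

sample_names <- function(cfg) sprintf("S%02d", seq_len(cfg$n_samples))

condition_of_samples <- function(cfg) {
  rep_len(cfg$conditions, cfg$n_samples)
}
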