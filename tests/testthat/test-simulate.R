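test_that("identical configs reproduce identical outputs", {
  cfg <- small_config(seed = 42)
  a <- simulate_multiome(cfg)
  b <- simulate_multiome(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$counts_peaks, b$counts_peaks)
  expect_identical(a$family_scores, b$family_scores)

  ra <- simulate_barcode_reads(a$clone_truth, cfg)
  rb <- simulate_barcode_reads(b$clone_truth, cfg)
  expect_identical(ra$reads, rb$reads)
  expect_identical(ra$consensus, rb$consensus)

  expect_identical(simulate_footprints(cfg), simulate_footprints(cfg))
  sa <- simulate_spatial(cfg)
  sb <- simulate_spatial(cfg)
  expect_identical(sa$counts, sb$counts)
  expect_identical(sa$tumors, sb$tumors)
})

test_that("count totals equal sampled depths", {
  sim <- simulate_multiome(small_config(seed = 2))
  expect_equal(as.vector(Matrix::rowSums(sim$counts_peaks)),
               as.numeric(sim$cells$depth_atac))
  expect_equal(as.vector(Matrix::rowSums(sim$counts_genes)),
               as.numeric(sim$cells$depth_rna))
})

test_that("planted intraclass correlation is recovered from latent scores", {
  cfg <- simulation_config(seed = 3, n_samples = 1, n_cells_per_sample = 5000,
                           n_peaks = 80, n_genes = 60, n_families = 3,
                           n_clones_per_sample = 50,
                           icc_per_family = c(0, 0.2, 0.5),
                           condition_shift_per_family = 0)
  sim <- simulate_multiome(cfg)
  for (f in 1:3) {
    icc_hat <- icc_estimate(sim$family_scores[, f], sim$cells$clone)
    expect_lt(abs(icc_hat - cfg$icc_per_family[f]), 0.05)
  }
})

test_that("zero ICC leaves clone labels uninformative for the heritability test", {
  cfg <- simulation_config(seed = 4, n_samples = 1, n_cells_per_sample = 600,
                           n_peaks = 60, n_genes = 40, n_families = 6,
                           n_clones_per_sample = 30, icc_per_family = 0,
                           condition_shift_per_family = 0)
  sim <- simulate_multiome(cfg)
  sc <- dplyr::bind_cols(tibble::tibble(cell = sim$cells$cell),
                         tibble::as_tibble(sim$family_scores))
  cvt <- clonal_variance_test(sc, tibble::tibble(cell = sim$cells$cell,
                                                 clone_id = sim$cells$clone),
                              n_perm = 200, seed = 1)
  expect_true(all(tidy(cvt)$p_value > 0.001))
})

test_that("high-memory clone fraction matches the planted mixture", {
  cfg <- simulation_config(seed = 5, n_samples = 10,
                           conditions = c("control", "recovered"),
                           n_cells_per_sample = 200, n_peaks = 50, n_genes = 40,
                           n_families = 2, n_clones_per_sample = 40,
                           icc_per_family = 0.5, delta_high = 2,
                           high_memory_fraction = 0.12)
  sim <- simulate_multiome(cfg)
  med <- tapply(sim$family_scores[, "AP1"], sim$cells$clone, median)
  info <- dplyr::distinct(sim$cells, clone, condition, high_memory)
  exposed <- info$clone[info$condition == "recovered"]
  high <- info$high_memory[match(exposed, info$clone)]

  # the exposed-clone medians are bimodal: the high-memory component sits
  # delta_high above the rest
  expect_lt(abs(median(med[exposed][high]) - median(med[exposed][!high]) -
                  cfg$delta_high), 0.5)

  # Monte-Carlo oracle of the generating mixture: clone medians are
  # clone_effect + shift (+ delta_high) + median of per-cell noise
  set.seed(1)
  per_clone <- length(sim$cells$cell) / nrow(info)
  mc <- replicate(20000, {
    is_high <- runif(1) < cfg$high_memory_fraction
    rnorm(1, sd = sqrt(0.5)) + 1 + if (is_high) 2 else 0 +
      median(rnorm(per_clone, sd = sqrt(0.5)))
  })
  frac_emp <- mean(med[exposed] > 2)
  frac_mc <- mean(mc > 2)
  expect_lt(abs(frac_emp - frac_mc), 0.06)
})

test_that("error-free barcode reads reproduce the clone consensus exactly", {
  cfg <- small_config(seed = 6, barcode_error_rate = 0)
  sim <- simulate_multiome(cfg)
  rd <- simulate_barcode_reads(sim$clone_truth, cfg)
  parsed <- parse_barcode_reads(rd$reads)
  expect_true(all(parsed$status == "ok"))
  truth <- rd$consensus[sim$clone_truth$clone[
    match(parsed$cell_barcode, sim$clone_truth$cell)]]
  expect_identical(parsed$barcode48, unname(truth))
})

test_that("per-base errors produce the binomial expected Hamming distance", {
  cfg <- small_config(seed = 7, barcode_error_rate = 0.01)
  sim <- simulate_multiome(cfg)
  rd <- simulate_barcode_reads(sim$clone_truth, cfg)
  ext <- extract_barcode_region(rd$reads$read_sequence, validate = FALSE)
  truth <- rd$consensus[sim$clone_truth$clone[
    match(rd$reads$cell_barcode, sim$clone_truth$cell)]]
  ok <- !is.na(ext$barcode48)
  ham <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                ext$barcode48[ok], truth[ok])
  expect_lt(abs(mean(ham) - 48 * 0.01), 0.06)
})

test_that("junk reads are rejected at the configured rate", {
  cfg <- small_config(seed = 8, junk_fraction = 0.1, barcode_error_rate = 0)
  sim <- simulate_multiome(cfg)
  rd <- simulate_barcode_reads(sim$clone_truth, cfg)
  parsed <- parse_barcode_reads(rd$reads)
  rejected <- mean(parsed$status != "ok")
  expect_lt(abs(rejected - 0.1), 0.02)
  # broken-anchor junk lands as no_anchor, or as invariant_mismatch when a
  # chance near-anchor 7-mer occurs downstream; all-G-UMI junk as umi_all_G
  expect_true(all(parsed$status %in%
                    c("ok", "no_anchor", "umi_all_G", "invariant_mismatch")))
  expect_gt(sum(parsed$status == "no_anchor"), 0)
  expect_gt(sum(parsed$status == "umi_all_G"), 0)
})

test_that("excessive error rate and empty inputs are rejected", {
  expect_error(simulation_config(barcode_error_rate = 0.6), "0.5")
  expect_error(simulation_config(n_cells_per_sample = 0), "cells")
  expect_error(simulation_config(n_clones_per_sample = 0), "clones")
  cfg <- small_config()
  empty_truth <- tibble::tibble(cell = character(), clone = character())
  expect_error(simulate_barcode_reads(empty_truth, cfg), "empty")
})

test_that("footprint cooccurrence = 1 plants a partner site in every AP-1 memory peak", {
  cfg <- simulation_config(seed = 9, n_peaks = 500, n_families = 3,
                           footprint = list(cooccurrence = c(ETS = 1, RUNX = 0.15)))
  fp <- simulate_footprints(cfg)
  ap1_peaks <- unique(fp$peak_id[fp$family == "AP1" & fp$planted_memory])
  ets_peaks <- unique(fp$peak_id[fp$family == "ETS" & fp$planted_memory])
  expect_true(all(ap1_peaks %in% ets_peaks))
  # planted memory deltas all clear the 0.2 threshold; nulls never do
  expect_true(all(abs(fp$planted_delta[fp$planted_memory]) >= 0.25))
  expect_true(all(abs(fp$planted_delta[!fp$planted_memory]) <= 0.1))
})

test_that("spatial tumors are disjoint and carry the Axin2 fold change", {
  cfg <- simulation_config(seed = 10, spatial = list(n_tumors = 4))
  sp <- simulate_spatial(cfg)
  expect_equal(nrow(sp$tumors), 4)
  d <- as.matrix(dist(sp$tumors[, c("x", "y")]))
  diag(d) <- Inf
  expect_true(all(d > 2 * cfg$spatial$tumor_radius_bins))
  # Axin2 share of reads much higher inside tumors
  ax <- sp$counts[, "Axin2"] / Matrix::rowSums(sp$counts)
  in_tumor <- rownames(sp$counts) %in% sp$bin_truth$bin_id
  expect_gt(mean(ax[in_tumor]), 3 * mean(ax[!in_tumor]))
})
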