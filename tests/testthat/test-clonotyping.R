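test_that("a read built from the forward oligo yields a 48-bp validated region", {
  set.seed(11)
  for (i in 1:20) {
    inst <- instantiate_oligo()
    read <- paste0(trace_anchor, inst)
    out <- extract_barcode_region(read)
    expect_equal(out$status, "ok")
    expect_equal(nchar(out$barcode48), 48L)
    # the extracted region is exactly the oligo's variable region
    expect_identical(out$barcode48, substr(inst, 27, 74))
  }
})

test_that("all-G UMIs are rejected", {
  set.seed(12)
  reads <- tibble::tibble(
    cell_barcode = c("c1", "c2"),
    umi = c("GGGGGGGGGG", "ACGTACGTAC"),
    read_sequence = paste0(trace_anchor, make_clone_barcodes(2))
  )
  parsed <- parse_barcode_reads(reads)
  expect_equal(parsed$status, c("umi_all_G", "ok"))
})

test_that("anchors with two substitutions are not found", {
  bar <- fixture_barcode(13)
  read <- paste0("TCGCCAT", bar)  # anchor with 2 substitutions
  # independent oracle: exhaustive Hamming scan over every 7-mer window
  expect_gte(min_anchor_distance(read), 2)
  out <- extract_barcode_region(read)
  expect_equal(out$status, "no_anchor")
  expect_true(is.na(out$barcode48))
})

test_that("short reads downstream of the anchor are flagged truncated", {
  bar <- fixture_barcode(14)
  read <- paste0(trace_anchor, substr(bar, 1, 30))
  expect_equal(extract_barcode_region(read)$status, "truncated")
})

test_that("invariant-dinucleotide failures are reported", {
  bar <- fixture_barcode(15)
  substr(bar, 5, 6) <- "AA"  # break the first invariant (offset 4: CT)
  read <- paste0(trace_anchor, bar)
  expect_equal(extract_barcode_region(read)$status, "invariant_mismatch")
})

test_that("triple counting applies the 5-read boundary exactly", {
  bar <- fixture_barcode(16)
  mk <- function(n, umi) tibble::tibble(cell_barcode = "c1", umi = umi,
                                        barcode48 = bar, status = "ok")[rep(1, n), ]
  five <- count_barcode_triples(mk(5, "AAAAAAAAAT"))
  expect_equal(nrow(five), 1)
  expect_equal(five$read_count, 5L)
  expect_equal(nrow(count_barcode_triples(mk(4, "AAAAAAAAAT"))), 0)
  empty <- count_barcode_triples(mk(5, "AAAAAAAAAT")[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("consensus calling handles singletons, satellites and far clones", {
  # single barcode is its own consensus
  b1 <- fixture_barcode(17)
  res <- call_clone_consensus(setNames(10, b1))
  expect_equal(res$consensus, b1)
  expect_equal(res$map$consensus, b1)

  # a 1-substitution satellite maps to the abundant centre; verified against
  # the brute-force 2x2 Levenshtein distance matrix
  b2 <- b1
  substr(b2, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(b1, 1, 1))[1]
  expect_equal(as.vector(utils::adist(b1, b2)), 1)
  res <- call_clone_consensus(setNames(c(100, 6), c(b1, b2)))
  expect_equal(res$consensus, b1)
  expect_equal(res$map$consensus[res$map$barcode48 == b2], b1)

  # three barcodes pairwise distance >= 9 stay distinct (identity mapping)
  set.seed(18)
  b3 <- make_clone_barcodes(3, min_distance = 9)
  expect_true(all(utils::adist(b3)[upper.tri(diag(3))] >= 9))
  res <- call_clone_consensus(setNames(c(30, 20, 10), b3))
  expect_setequal(res$consensus, b3)
  expect_identical(res$map$consensus, res$map$barcode48)
})

test_that("step-2 collapse merges near consensus sequences onto the more abundant", {
  b1 <- fixture_barcode(19)
  b2 <- b1
  substr(b2, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(b1, 2, 2))[1]
  # with d_assign = 0 step 1 is the identity, so both survive to step 2,
  # which collapses the distance-1 pair onto the more abundant member
  res <- call_clone_consensus(setNames(c(50, 40), c(b1, b2)),
                              d_assign = 0, d_collapse = 2)
  expect_equal(res$consensus, b1)
  expect_equal(unique(res$map$consensus), b1)
})

test_that("clustering is invariant to input order and abundance ties break lexicographically", {
  set.seed(20)
  bars <- make_clone_barcodes(4, min_distance = 9)
  counts <- tibble::tibble(barcode48 = bars, reads = c(10, 10, 5, 2))
  a <- call_clone_consensus(counts)
  b <- call_clone_consensus(counts[c(3, 1, 4, 2), ])
  expect_identical(a$consensus, b$consensus)
  expect_identical(dplyr::arrange(a$map, barcode48),
                   dplyr::arrange(b$map, barcode48))

  # equal-abundance satellite pair: winner is the lexicographically smaller
  b1 <- fixture_barcode(21)
  b2 <- b1
  substr(b2, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(b1, 1, 1))[1]
  res <- call_clone_consensus(setNames(c(7, 7), c(b1, b2)))
  expect_equal(res$consensus, min(b1, b2))
})

test_that("clones are assigned to the majority sample and small clones dropped", {
  set.seed(22)
  bars <- make_clone_barcodes(3, min_distance = 9)
  map <- tibble::tibble(barcode48 = bars, consensus = bars)
  mk_triples <- function(cells, bar) {
    tibble::tibble(cell_barcode = cells,
                   umi = sprintf("U%03d", seq_along(cells)),
                   barcode48 = bar, read_count = 6L)
  }
  # clone 1: 19 cells in S1 + 1 cell in S2; clone 2: 4 cells (too small);
  # clone 3: one cell with a tie between clones 2 and 3
  triples <- dplyr::bind_rows(
    mk_triples(sprintf("a%02d", 1:19), bars[1]),
    mk_triples("b01", bars[1]),
    mk_triples(sprintf("c%02d", 1:4), bars[2]),
    tibble::tibble(cell_barcode = "t01", umi = c("U900", "U901"),
                   barcode48 = bars[2:3], read_count = 6L)
  )
  cells <- tibble::tibble(
    cell = c(sprintf("a%02d", 1:19), "b01", sprintf("c%02d", 1:4), "t01"),
    sample = c(rep("S1", 19), "S2", rep("S1", 4), "S1")
  )
  ca <- assign_clones(triples, map, cells, min_cells = 5)
  expect_equal(nrow(ca$clones), 1)
  expect_equal(ca$clones$sample, "S1")
  expect_equal(ca$clones$n_cells, 19L)
  expect_true(all(sprintf("a%02d", 1:19) %in% ca$cell_clones$cell))
  reasons <- setNames(ca$unassigned$reason, ca$unassigned$cell)
  expect_equal(unname(reasons["b01"]), "cross_sample")
  expect_equal(unname(reasons["t01"]), "ambiguous")
  expect_true(all(reasons[sprintf("c%02d", 1:4)] == "small_clone"))
})

test_that("simulated clones are recovered with high fidelity at 1% error", {
  cfg <- simulation_config(seed = 23, n_samples = 2, n_cells_per_sample = 120,
                           n_peaks = 50, n_genes = 40, n_families = 2,
                           n_clones_per_sample = 5, barcode_error_rate = 0.01)
  sim <- simulate_multiome(cfg)
  rd <- simulate_barcode_reads(sim$clone_truth, cfg)
  ca <- call_clones(rd$reads, sim$cells)
  expect_equal(nrow(ca$clones), length(unique(sim$cells$clone)))
  joined <- dplyr::inner_join(ca$cell_clones, sim$clone_truth, by = "cell") |>
    dplyr::inner_join(ca$clones, by = "clone_id")
  planted_of <- setNames(names(rd$consensus), rd$consensus)
  expect_gte(mean(planted_of[joined$consensus] == joined$clone), 0.99)
  # every retained cell belongs to exactly one clone
  expect_equal(anyDuplicated(ca$cell_clones$cell), 0)
})
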