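toy_sites <- function(deltas, family = "AP1", control = 0.3) {
  tibble::tibble(
    site_id = sprintf("s%03d", seq_along(deltas)),
    peak_id = sprintf("p%03d", seq_along(deltas)),
    bin_start = 0, family = family,
    score_control = control,
    score_case = control + deltas
  )
}

test_that("memory calls use an inclusive 0.2 boundary in both directions", {
  s <- toy_sites(c(0.20, 0.19, 0.5, -0.20, -0.19))
  gain <- call_memory_sites(s, "case", "control")
  expect_equal(gain$memory, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(gain$delta, c(0.20, 0.19, 0.5, -0.20, -0.19))
  loss <- call_memory_sites(s, "case", "control", direction = "loss")
  expect_equal(loss$memory, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("simulator-planted memory sites are called perfectly", {
  fp <- simulate_footprints(small_config(seed = 70))
  ms <- call_memory_sites(fp, "recovered", "control")
  expect_true(all(ms$memory[ms$planted_memory]))
  expect_true(all(!ms$memory[!ms$planted_memory]))
})

test_that("co-binding odds ratios match hand arithmetic", {
  # build a memory table with a prescribed 2x2 peak classification
  mk <- function(both, first, second, neither) {
    n <- both + first + second + neither
    peaks <- sprintf("p%04d", seq_len(n))
    a_peaks <- peaks[seq_len(both + first)]
    b_peaks <- c(peaks[seq_len(both)],
                 peaks[both + first + seq_len(second)])
    sites <- dplyr::bind_rows(
      tibble::tibble(peak_id = a_peaks, family = "A"),
      tibble::tibble(peak_id = b_peaks, family = "B"))
    sites$site_id <- sprintf("s%04d", seq_len(nrow(sites)))
    sites$bin_start <- 0
    sites$memory <- TRUE
    list(sites = sites, peaks = peaks)
  }
  bal <- mk(10, 10, 10, 10)
  cb <- cobinding_matrix(bal$sites, peaks = bal$peaks)
  expect_equal(cb$log2_or, c(0, 0))

  printed <- mk(20, 5, 4, 100)
  cb2 <- cobinding_matrix(printed$sites, peaks = printed$peaks)
  expect_equal(cb2$odds_ratio[1], 100)
  expect_equal(cb2$log2_or[1], log2(100))

  # mutual exclusion forces a strongly negative log2 OR via Haldane correction
  excl <- mk(0, 15, 15, 70)
  cb3 <- cobinding_matrix(excl$sites, peaks = excl$peaks)
  # Haldane-corrected: (0.5 * 70.5) / (15.5 * 15.5), log2 ~ -2.77
  expect_lt(cb3$log2_or[1], -2)
  expect_equal(cb3$odds_ratio[1], (0.5 * 70.5) / (15.5 * 15.5))
})

test_that("co-binding is exactly symmetric in the pair", {
  fp <- simulate_footprints(small_config(seed = 71))
  ms <- call_memory_sites(fp, "recovered", "control")
  cb <- cobinding_matrix(ms)
  swapped <- dplyr::rename(cb, family_a = family_b, family_b = family_a)
  joined <- dplyr::inner_join(cb, swapped, by = c("family_a", "family_b"))
  expect_identical(joined$log2_or.x, joined$log2_or.y)
})

test_that("independent planting gives near-zero mean log2 odds ratio", {
  cfg <- simulation_config(seed = 72, n_peaks = 2000)  # cooccurrence defaults to independence
  fp <- simulate_footprints(cfg)
  ms <- call_memory_sites(fp, "recovered", "control")
  cb <- cobinding_matrix(ms, peaks = sprintf("peak_%05d", seq_len(2000)))
  expect_lt(abs(mean(cb$log2_or)), 0.3)
})

test_that("quantile normalisation matches the percentile oracle and clips", {
  d <- tibble::tibble(log2_or = as.numeric(1:10))
  out <- normalize_cobinding(d)
  q <- quantile(1:10, c(0.1, 0.9), names = FALSE)  # 1.9 and 9.1
  expect_equal(q, c(1.9, 9.1))
  expect_equal(out$cobinding_score[2], (2 - 1.9) / (9.1 - 1.9))
  expect_equal(out$cobinding_score[10], 1)  # above q90: clipped
  expect_equal(out$cobinding_score[1], 0)   # below q10: clipped

  neg <- normalize_cobinding(tibble::tibble(log2_or = -(1:10)))
  expect_equal(neg$cobinding_score[2], -(2 - 1.9) / (9.1 - 1.9))
  expect_true(all(neg$cobinding_score <= 0 & neg$cobinding_score >= -1))

  expect_warning(deg <- normalize_cobinding(tibble::tibble(log2_or = rep(2, 4))),
                 "degenerate")
  expect_equal(deg$cobinding_score, rep(0, 4))

  # sign of the score always matches the sign of the log2 OR
  set.seed(73)
  mixed <- normalize_cobinding(tibble::tibble(log2_or = rnorm(200)))
  expect_true(all(sign(mixed$cobinding_score) == sign(mixed$log2_or) |
                    mixed$cobinding_score == 0))

  # approximate idempotence: after one pass about 10% of each sign's mass sits
  # exactly at the clip boundaries, so the next pass's 10th/90th percentiles
  # fall at (or interpolate just inside) 0 and 1 and values move only slightly
  once <- mixed$cobinding_score
  twice <- normalize_cobinding(tibble::tibble(log2_or = once))$cobinding_score
  expect_lt(max(abs(twice - once)), 0.15)
  expect_lt(median(abs(twice - once)), 0.05)
})

test_that("nearest reference distances follow midpoint arithmetic", {
  sites <- tibble::tibble(
    site_id = paste0("s", 1:4),
    peak_id = c("p1", "p1", "p1", "p2"),
    bin_start = c(100, 120, 200, 40),
    family = c("ETS", "AP1", "AP1", "ETS"),
    memory = TRUE
  )
  d <- nearest_reference_distance(sites, reference = "AP1")
  expect_equal(nrow(d), 1)  # the p2 site has no reference site in its peak
  expect_equal(d$distance, 20)

  colocated <- dplyr::mutate(sites[1:2, ], bin_start = 100)
  expect_equal(nearest_reference_distance(colocated)$distance, 0)
})

test_that("planted cooccurrence yields adjacent partner sites", {
  cfg <- simulation_config(seed = 74, n_peaks = 800, n_families = 2,
                           footprint = list(cooccurrence = c(ETS = 1)))
  fp <- simulate_footprints(cfg)
  ms <- call_memory_sites(fp, "recovered", "control")
  d <- nearest_reference_distance(dplyr::filter(ms, memory))
  sm <- summarize_reference_distance(d)
  expect_equal(sm$fraction_adjacent[sm$family == "ETS"], 1)
})

test_that("the performance sweep is monotone and finds perfect separation", {
  set.seed(75)
  n <- 250
  labels <- tibble::tibble(peak_id = sprintf("p%04d", 1:(2 * n)),
                           differential = rep(c(TRUE, FALSE), each = n))
  deltas <- tibble::tibble(peak_id = labels$peak_id,
                           delta = c(rnorm(n, 0.3, 0.1), rnorm(n, 0, 0.1)))
  curve <- footprint_performance_curve(deltas, labels)
  expect_true(all(diff(curve$sensitivity) <= 1e-12))
  expect_true(all(diff(curve$specificity) >= -1e-12))

  # brute-force accuracy oracle over the same grid
  oracle <- sapply(curve$threshold, function(t) {
    mean((abs(deltas$delta) >= t) == labels$differential)
  })
  expect_equal(curve$accuracy, oracle)

  sep <- tibble::tibble(peak_id = labels$peak_id,
                        delta = ifelse(labels$differential, 0.5, 0))
  sc <- footprint_performance_curve(sep, labels)
  expect_true(any(sc$sensitivity == 1 & sc$specificity == 1))

  # identical deltas degenerate to all-or-nothing
  flat <- tibble::tibble(peak_id = labels$peak_id, delta = 0.4)
  fc <- footprint_performance_curve(flat, labels, thresholds = c(0, 0.4, 0.41))
  expect_equal(fc$sensitivity, c(1, 1, 0))
  expect_equal(fc$specificity, c(0, 0, 1))

  expect_warning(
    footprint_performance_curve(deltas,
                                dplyr::mutate(labels, differential = FALSE)),
    "no positive")
})
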