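# Shared fixtures and independent oracles used across the suite.

small_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_samples = 2, n_cells_per_sample = 60,
                    n_peaks = 150, n_genes = 120, n_families = 4,
                    n_clones_per_sample = 4, ...)
}

# Dense brute-force deviation-score oracle: plain loops, dense matrices,
# stats::sd. Independent of the sparse running-moment implementation.
dense_deviation_oracle <- function(counts, annotation, backgrounds) {
  x <- as.matrix(counts)
  w_all <- as.matrix(annotation)
  depth <- rowSums(x)
  tot <- colSums(x)
  e <- outer(depth, tot) / sum(x)
  z <- matrix(NA_real_, nrow(x), ncol(w_all),
              dimnames = list(rownames(x), colnames(w_all)))
  for (k in seq_len(ncol(w_all))) {
    w <- w_all[, k]
    y <- as.vector((x %*% w - e %*% w) / (e %*% w))
    yb <- sapply(seq_len(ncol(backgrounds)), function(b) {
      wb <- numeric(length(w))
      for (f in which(w != 0)) {
        g <- backgrounds[f, b]
        wb[g] <- wb[g] + w[f]
      }
      as.vector((x %*% wb - e %*% wb) / (e %*% wb))
    })
    m <- rowMeans(yb)
    s <- apply(yb, 1, sd)
    zz <- (y - m) / s
    zz[s == 0 & (y - m) == 0] <- 0
    z[, k] <- zz
  }
  z
}

# One-way ANOVA method-of-moments intraclass correlation estimate.
icc_estimate <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  ni <- as.vector(table(group))
  n <- length(values)
  gm <- mean(values)
  mi <- tapply(values, group, mean)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[group])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  n0 <- (n - sum(ni^2) / n) / (k - 1)
  (msb - msw) / (msb + (n0 - 1) * msw)
}

# Clonal-variance statistic computed independently (loops + stats::sd).
clonal_variance_stat <- function(values, clone) {
  sds <- tapply(values, clone, sd)
  median(sds)^2
}

# Minimum Hamming distance of a 7-mer pattern over all windows of a read.
min_anchor_distance <- function(read, anchor = "TAGACAT") {
  a <- strsplit(anchor, "")[[1]]
  r <- strsplit(read, "")[[1]]
  la <- length(a)
  if (length(r) < la) return(Inf)
  min(vapply(seq_len(length(r) - la + 1), function(i) {
    sum(r[i:(i + la - 1)] != a)
  }, numeric(1)))
}

# A valid random 48-mer barcode (invariant dinucleotides in place).
fixture_barcode <- function(seed) {
  set.seed(seed)
  make_clone_barcodes(1)
}
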