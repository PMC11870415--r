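#' Call memory footprints from per-condition score changes
#'
#' A site is a memory footprint when its footprint score changes by at least
#' `threshold` between a condition and its control: gains use
#' `score(condition) - score(control) >= threshold` (inclusive), losses
#' `<= -threshold`.
#'
#' @param sites Footprint site tibble with columns `site_id`, `peak_id`,
#'   `bin_start`, `family` and per-condition score columns
#'   `score_<condition>` (scores in \[0, 1\], pre-filtered upstream to sites
#'   whose maximum score reaches 0.2 in some condition).
#' @param condition,control Condition labels naming the score columns.
#' @param threshold Minimum change (default 0.2).
#' @param direction `"gain"` or `"loss"`.
#' @return `sites` with `delta` and logical `memory` columns appended.
#' @examples
#' s <- tibble::tibble(site_id = "s1", peak_id = "p1", bin_start = 0,
#'                     family = "AP1", score_control = 0.3,
#'                     score_recovered = 0.55)
#' call_memory_sites(s, "recovered", "control")
#' @export
call_memory_sites <- function(sites, condition, control, threshold = 0.2,
                              direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  ca <- paste0("score_", condition)
  co <- paste0("score_", control)
  stopifnot(all(c(ca, co) %in% names(sites)))
  delta <- sites[[ca]] - sites[[co]]
  memory <- switch(direction,
                   gain = delta >= threshold,
                   loss = delta <= -threshold)
  mutate(sites, delta = delta, memory = memory)
}

#' Peak-level co-binding odds ratios between family pairs
#'
#' For every ordered pair of families, peaks are cross-classified as carrying
#' a memory site of both families, the first only, the second only, or
#' neither, and the odds ratio of the 2x2 table
#' `(both x neither) / (first_only x second_only)` is computed and
#' log2-transformed. When any table cell is zero, the Haldane correction
#' (+0.5 to every cell) is applied. The statistic is symmetric in the pair.
#'
#' @param sites Memory-called site tibble from [call_memory_sites()].
#' @param peaks Character vector of all peaks in the universe (default: all
#'   peaks appearing in `sites`).
#' @param families Families to pair (default: all in `sites`).
#' @return Tibble `family_a`, `family_b`, `both`, `first_only`,
#'   `second_only`, `neither`, `odds_ratio`, `log2_or`, one row per ordered
#'   pair.
#' @export
cobinding_matrix <- function(sites, peaks = NULL, families = NULL) {
  stopifnot(all(c("peak_id", "family", "memory") %in% names(sites)))
  peaks <- peaks %||% sort(unique(sites$peak_id))
  families <- families %||% sort(unique(sites$family))
  n_peaks <- length(peaks)

  mem_peaks <- sites |>
    filter(.data$memory) |>
    distinct(.data$family, .data$peak_id)
  mem_list <- map(setNames(families, families), function(f) {
    unique(mem_peaks$peak_id[mem_peaks$family == f])
  })

  pairs <- expand_grid(family_a = families, family_b = families) |>
    filter(.data$family_a != .data$family_b)
  stats <- pmap(pairs, function(family_a, family_b) {
    pa <- mem_list[[family_a]]
    pb <- mem_list[[family_b]]
    both <- length(intersect(pa, pb))
    first_only <- length(pa) - both
    second_only <- length(pb) - both
    neither <- n_peaks - both - first_only - second_only
    cells <- c(both, first_only, second_only, neither)
    if (any(cells == 0)) cells <- cells + 0.5
    or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    tibble(both = both, first_only = first_only, second_only = second_only,
           neither = neither, odds_ratio = or, log2_or = log2(or))
  })
  bind_cols(pairs, list_rbind(stats))
}

#' Quantile-normalise co-binding log2 odds ratios
#'
#' Scales positive log2 odds ratios linearly between the 10th and 90th
#' percentiles of all positive values in the pooling set onto \[0, 1\]
#' (clipped), and negative values analogously onto \[-1, 0\]; zeros stay 0.
#' The pooling set is whatever is passed in: pool all pairs and all
#' timepoints of an experiment by row-binding their tables first.
#' Percentiles use linear interpolation. A degenerate range (equal
#' percentiles) maps those values to 0 with a warning.
#'
#' @param cobinding Tibble with a `log2_or` column (e.g. from
#'   [cobinding_matrix()], possibly several row-bound timepoints).
#' @param probs Lower and upper percentile (default `c(0.1, 0.9)`).
#' @return The input with a `cobinding_score` column in \[-1, 1\] appended.
#' @export
normalize_cobinding <- function(cobinding, probs = c(0.1, 0.9)) {
  v <- cobinding$log2_or
  score <- numeric(length(v))
  scale_side <- function(vals, sign) {
    q <- quantile(vals * sign, probs, names = FALSE, type = 7)
    if (q[2] == q[1]) {
      warn("degenerate quantile range; values mapped to 0.")
      return(rep(0, length(vals)))
    }
    sign * pmin(1, pmax(0, (vals * sign - q[1]) / (q[2] - q[1])))
  }
  pos <- which(v > 0)
  neg <- which(v < 0)
  if (length(pos)) score[pos] <- scale_side(v[pos], 1)
  if (length(neg)) score[neg] <- scale_side(v[neg], -1)
  mutate(cobinding, cobinding_score = score)
}

#' Distance from memory sites to the nearest reference-family memory site
#'
#' Within each peak containing a memory site of the reference family
#' (AP-1 by default), computes for every other family's memory site the
#' distance in bp between bin midpoints to the nearest reference site.
#' Sites in peaks lacking a reference memory site are excluded.
#'
#' @param sites Memory-called site tibble from [call_memory_sites()].
#' @param reference Reference family (default `"AP1"`).
#' @param bin_size Footprint bin width in bp (default 10; midpoint =
#'   `bin_start + bin_size / 2`).
#' @return Tibble `site_id`, `peak_id`, `family`, `distance`.
#' @export
nearest_reference_distance <- function(sites, reference = "AP1",
                                       bin_size = 10) {
  mem <- filter(sites, .data$memory)
  ref <- mem |>
    filter(.data$family == reference) |>
    mutate(mid = .data$bin_start + bin_size / 2)
  ref_mids <- split(ref$mid, ref$peak_id)
  out <- mem |>
    filter(.data$family != reference, .data$peak_id %in% names(ref_mids))
  mid <- out$bin_start + bin_size / 2
  out$distance <- map_dbl(seq_len(nrow(out)), function(i) {
    min(abs(mid[i] - ref_mids[[out$peak_id[i]]]))
  })
  select(out, "site_id", "peak_id", "family", "distance")
}

#' Summarise adjacency to the reference family
#'
#' @param distances Output of [nearest_reference_distance()].
#' @param adjacent Distance in bp under which two sites count as adjacent
#'   (default 20).
#' @return Tibble `family`, `n_sites`, `fraction_adjacent`.
#' @export
summarize_reference_distance <- function(distances, adjacent = 20) {
  distances |>
    group_by(.data$family) |>
    summarise(n_sites = n(),
              fraction_adjacent = mean(.data$distance < adjacent),
              .groups = "drop")
}

#' Collapse footprint score changes to one value per peak
#'
#' Collapses a family's sites to a single per-peak change, taking the delta
#' of largest magnitude (overlapping motifs having been merged into sites
#' upstream).
#'
#' @param sites Memory-called site tibble with a `delta` column.
#' @param family Family to collapse (default `"AP1"`).
#' @return Tibble `peak_id`, `delta`.
#' @export
collapse_peak_delta <- function(sites, family = "AP1") {
  sites |>
    filter(.data$family == !!family) |>
    group_by(.data$peak_id) |>
    summarise(delta = .data$delta[which.max(abs(.data$delta))],
              .groups = "drop")
}

#' Sensitivity/specificity sweep of footprint-change thresholds
#'
#' Evaluates how well the magnitude of the per-peak footprint score change
#' predicts an independent differential label (e.g. differential TF ChIP
#' peaks): at each threshold `t`, peaks with `|delta| >= t` are predicted
#' differential, and sensitivity, specificity and accuracy are reported.
#'
#' @param peak_deltas Tibble `peak_id`, `delta` (one row per labeled peak,
#'   e.g. from [collapse_peak_delta()]).
#' @param labels Tibble `peak_id`, `differential` (logical or 0/1).
#' @param thresholds Numeric grid; defaults to 0 and every distinct observed
#'   `|delta|`.
#' @return Tibble `threshold`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`. Sensitivity is `NA` (with a warning) when
#'   there are no positive labels.
#' @export
footprint_performance_curve <- function(peak_deltas, labels,
                                        thresholds = NULL) {
  joined <- inner_join(peak_deltas, labels, by = "peak_id")
  if (nrow(joined) == 0) abort("no labeled peaks with a delta.")
  y <- as.logical(joined$differential)
  a <- abs(joined$delta)
  thresholds <- thresholds %||% sort(unique(c(0, a)))
  if (!any(y)) warn("no positive labels; sensitivity undefined.")
  list_rbind(map(thresholds, function(t) {
    pred <- a >= t
    tp <- sum(pred & y); fp <- sum(pred & !y)
    tn <- sum(!pred & !y); fn <- sum(!pred & y)
    tibble(threshold = t, tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
           accuracy = (tp + tn) / length(y))
  }))
}
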