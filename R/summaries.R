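#' Per-sample condition summary of deviation scores
#'
#' Averages single-cell scores across all cells of each sample, computes each
#' sample's change relative to the mean of the control samples, and tests
#' each non-control condition against control with a two-sample t-test on
#' the per-sample means. p-values are computed for the `n_top` most variable
#' families (variance of per-cell scores across all cells) and adjusted with
#' Benjamini-Hochberg across those families within each condition. Samples
#' with fewer than `min_cells` cells are flagged (`included = FALSE`) for
#' exclusion from heatmap-style outputs but still enter the tests.
#'
#' @param scores Wide scores tibble from [deviation_scores()] (a `cell`
#'   column plus one column per family).
#' @param cells Tibble with columns `cell`, `sample`, `condition`; optionally
#'   `cell_type` (filtered to `target_type` when given).
#' @param control Control condition label (default `"control"`).
#' @param n_top Number of most-variable families tested (default 50).
#' @param min_cells Per-sample cell threshold for the `included` flag
#'   (default 200).
#' @param target_type Optional cell type to subset to.
#' @return An object of class `"condition_summary"`: list with
#'   `sample_means` (tibble `family`, `sample`, `condition`, `n_cells`,
#'   `mean`, `change`, `included`) and `tests` (tibble `family`, `condition`,
#'   `mean_change`, `p_value`, `fdr`, `tested`). `tidy()` returns `tests`.
#' @export
condition_summary <- function(scores, cells, control = "control",
                              n_top = 50L, min_cells = 200L,
                              target_type = NULL) {
  stopifnot(all(c("cell", "sample", "condition") %in% names(cells)))
  if (!is.null(target_type)) {
    stopifnot("cell_type" %in% names(cells))
    cells <- filter(cells, .data$cell_type == target_type)
  }
  fams <- setdiff(names(scores), "cell")
  long <- scores |>
    inner_join(select(cells, "cell", "sample", "condition"), by = "cell") |>
    pivot_longer(all_of(fams), names_to = "family", values_to = "score")

  if (!control %in% long$condition) {
    abort(sprintf("control condition '%s' absent from `cells`.", control))
  }

  sample_means <- long |>
    group_by(.data$family, .data$sample, .data$condition) |>
    summarise(n_cells = n(), mean = mean(.data$score, na.rm = TRUE),
              .groups = "drop")
  control_mean <- sample_means |>
    filter(.data$condition == control) |>
    group_by(.data$family) |>
    summarise(control_mean = mean(.data$mean), .groups = "drop")
  sample_means <- sample_means |>
    left_join(control_mean, by = "family") |>
    mutate(change = .data$mean - .data$control_mean,
           included = .data$n_cells >= min_cells) |>
    select(-"control_mean")

  # most variable families across all cells
  fam_var <- long |>
    group_by(.data$family) |>
    summarise(variance = var(.data$score, na.rm = TRUE), .groups = "drop") |>
    arrange(desc(.data$variance), .data$family)
  top <- head(fam_var$family, n_top)

  tests <- sample_means |>
    filter(.data$condition != control) |>
    group_by(.data$family, .data$condition) |>
    summarise(mean_change = mean(.data$change),
              p_value = {
        a <- .data$mean
        b <- sample_means$mean[sample_means$family == .data$family[1] &
                                 sample_means$condition == control]
        if (length(a) >= 2 && length(b) >= 2) t.test(a, b)$p.value
        else NA_real_
      }, .groups = "drop") |>
    mutate(tested = .data$family %in% top)
  tests <- tests |>
    group_by(.data$condition) |>
    mutate(fdr = {
      p <- if_else(.data$tested, .data$p_value, NA_real_)
      out <- rep(NA_real_, length(p))
      ok <- !is.na(p)
      out[ok] <- p.adjust(p[ok], method = "BH")
      out
    }) |>
    ungroup()

  structure(list(sample_means = sample_means, tests = tests,
                 control = control, n_top = n_top),
            class = "condition_summary")
}

#' @exportS3Method base::print
print.condition_summary <- function(x, ...) {
  cat("<condition_summary> ", n_distinct(x$tests$family), " families, ",
      n_distinct(x$sample_means$sample), " samples; control = ",
      x$control, "\n", sep = "")
  print(head(arrange(x$tests, .data$fdr), 10))
  invisible(x)
}

#' @rdname condition_summary
#' @param x A `condition_summary`.
#' @param ... Unused.
#' @export
tidy.condition_summary <- function(x, ...) x$tests

#' Fraction of activated cells per sample
#'
#' Activated cells are those whose deviation score for `family` exceeds
#' `threshold` (strict inequality). The fraction is over all scored cells of
#' the sample.
#'
#' @param scores Wide scores tibble from [deviation_scores()].
#' @param cells Tibble with `cell`, `sample`, `condition`.
#' @param family Family (column) name to threshold.
#' @param threshold Activation threshold (default 1.5).
#' @return Tibble `sample`, `condition`, `n_cells`, `n_activated`, `fraction`.
#' @export
activated_fraction <- function(scores, cells, family, threshold = 1.5) {
  stopifnot(family %in% names(scores))
  scores |>
    select("cell", score = all_of(family)) |>
    inner_join(select(cells, "cell", "sample", "condition"), by = "cell") |>
    group_by(.data$sample, .data$condition) |>
    summarise(n_cells = n(),
              n_activated = sum(.data$score > threshold, na.rm = TRUE),
              fraction = .data$n_activated / .data$n_cells,
              .groups = "drop")
}

#' Kolmogorov-Smirnov test on downsampled score distributions
#'
#' Randomly downsamples each of two conditions to `n` cells (all cells, with
#' a flag, when a condition has fewer) and compares the score distributions
#' with a two-sample KS test. Downsampling equalises power across conditions
#' of very different size.
#'
#' @param scores Wide scores tibble.
#' @param cells Tibble with `cell` and `condition`.
#' @param family Family column to test (or several).
#' @param conditions Length-2 character vector of conditions to compare.
#' @param n Cells per condition after downsampling (default 500).
#' @param seed RNG seed.
#' @return Tibble `family`, `condition_a`, `condition_b`, `n_a`, `n_b`,
#'   `downsampled`, `statistic`, `p_value`.
#' @export
downsampled_ks <- function(scores, cells, family, conditions, n = 500L,
                           seed = 1L) {
  stopifnot(length(conditions) == 2, all(family %in% names(scores)))
  joined <- scores |>
    inner_join(select(cells, "cell", "condition"), by = "cell") |>
    filter(.data$condition %in% conditions)
  set.seed(seed)
  take <- function(v, n) if (length(v) > n) sample(v, n) else v
  list_rbind(map(family, function(f) {
    a <- joined |> filter(.data$condition == conditions[1]) |> pull(all_of(f))
    b <- joined |> filter(.data$condition == conditions[2]) |> pull(all_of(f))
    a2 <- take(a[!is.na(a)], n)
    b2 <- take(b[!is.na(b)], n)
    ks <- suppressWarnings(ks.test(a2, b2))
    tibble(family = f, condition_a = conditions[1],
           condition_b = conditions[2],
           n_a = length(a2), n_b = length(b2),
           downsampled = length(a2) == n && length(b2) == n,
           statistic = unname(ks$statistic), p_value = ks$p.value)
  }))
}
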