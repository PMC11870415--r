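#' Simulate per-condition TF footprint score tables
#'
#' Places 10-bp-binned footprint sites inside peaks for the AP-1 reference
#' family and partner families, planting "memory" sites whose score gains
#' between control and the exposed condition fall in `delta_memory` (all above
#' the 0.2 call threshold) and background sites whose changes fall in
#' `delta_null`. Per partner family, the probability that a peak carrying an
#' AP-1 memory site also carries a partner memory site is the configured
#' `cooccurrence`; partner sites in AP-1 memory peaks are placed within one
#' bin of the AP-1 site. The partner marginal memory rate is preserved, so
#' setting `cooccurrence = partner_rate` yields independence (odds ratio 1).
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `site_id`, `peak_id`, `bin_start`, `family`,
#'   one `score_<condition>` column per condition, and the planted-truth
#'   columns `planted_memory` and `planted_delta` (absent from real data).
#' @examples
#' fp <- simulate_footprints(simulation_config(seed = 1, n_peaks = 200))
#' head(fp)
#' @export
simulate_footprints <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  fpc <- cfg$footprint
  set.seed(artifact_seed(cfg, 3L))

  fams <- family_names(cfg$n_families)
  ref <- fams[1]
  partners <- fams[-1]
  cooc <- fpc$cooccurrence %||% fpc$partner_rate
  if (is.null(names(cooc))) {
    cooc <- setNames(rep_len(cooc, length(partners)), partners)
  } else {
    missing <- setdiff(partners, names(cooc))
    cooc <- c(cooc, setNames(rep(fpc$partner_rate, length(missing)), missing))
  }

  peak_ids <- sprintf("peak_%05d", seq_len(cfg$n_peaks))
  bin_starts <- seq(0L, fpc$peak_width - fpc$bin_size, by = fpc$bin_size)
  n_bins <- length(bin_starts)

  rdelta <- function(n, range) runif(n, range[1], range[2])

  ap1_mem <- runif(cfg$n_peaks) < fpc$ap1_rate
  ap1_bin <- sample.int(n_bins, cfg$n_peaks, replace = TRUE)

  rows <- list()
  add <- function(peak_idx, bin_idx, family, delta, memory) {
    n <- length(peak_idx)
    if (n == 0) return(invisible(NULL))
    ctrl <- if (all(memory)) runif(n, 0.05, 0.5) else runif(n, 0.3, 0.8)
    rows[[length(rows) + 1]] <<- tibble(
      peak_id = peak_ids[peak_idx],
      bin_start = bin_starts[bin_idx],
      family = family,
      score_control = ctrl,
      score_case = pmin(1, pmax(0, ctrl + delta)),
      planted_memory = memory,
      planted_delta = delta
    )
  }

  # AP-1 memory sites
  idx <- which(ap1_mem)
  add(idx, ap1_bin[idx], ref, rdelta(length(idx), fpc$delta_memory),
      rep(TRUE, length(idx)))

  for (f in partners) {
    p_given_ap1 <- cooc[[f]]
    # preserve the marginal partner_rate
    p_given_none <- if (fpc$ap1_rate >= 1) 0 else
      (fpc$partner_rate - fpc$ap1_rate * p_given_ap1) / (1 - fpc$ap1_rate)
    p_given_none <- min(1, max(0, p_given_none))
    u <- runif(cfg$n_peaks)
    mem_f <- if_else(ap1_mem, u < p_given_ap1, u < p_given_none)
    idx <- which(mem_f)
    if (length(idx)) {
      # partner sites in AP-1 memory peaks sit within one bin of the AP-1 site
      off <- sample(-1:1, length(idx), replace = TRUE)
      bin <- if_else(ap1_mem[idx],
                     pmin(n_bins, pmax(1L, ap1_bin[idx] + off)),
                     sample.int(n_bins, length(idx), replace = TRUE))
      add(idx, bin, f, rdelta(length(idx), fpc$delta_memory),
          rep(TRUE, length(idx)))
    }
  }

  # background (non-memory) sites for every family
  for (f in fams) {
    idx <- which(runif(cfg$n_peaks) < fpc$background_site_rate)
    if (length(idx)) {
      add(idx, sample.int(n_bins, length(idx), replace = TRUE), f,
          rdelta(length(idx), fpc$delta_null), rep(FALSE, length(idx)))
    }
  }

  out <- list_rbind(rows)
  # one site per (peak, family, bin): drop background sites colliding with a
  # planted memory site of the same family
  out <- out |>
    arrange(desc(.data$planted_memory)) |>
    distinct(.data$peak_id, .data$family, .data$bin_start, .keep_all = TRUE) |>
    arrange(.data$peak_id, .data$bin_start, .data$family)
  out$site_id <- sprintf("site_%06d", seq_len(nrow(out)))

  exposed <- setdiff(cfg$conditions, cfg$conditions[1])[1]
  if (is.na(exposed)) exposed <- "case"
  names(out)[names(out) == "score_control"] <-
    paste0("score_", cfg$conditions[1])
  names(out)[names(out) == "score_case"] <- paste0("score_", exposed)
  select(out, "site_id", "peak_id", "bin_start", "family",
         dplyr::starts_with("score_"), "planted_memory", "planted_delta")
}
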