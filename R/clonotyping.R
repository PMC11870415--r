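#' Clonal barcode sequence constants
#'
#' `trace_anchor` is the 7-bp vector sequence immediately 5' of the expressed
#' 48-bp clonal barcode; the parser locates it allowing one mismatch.
#' `trace_forward_oligo` is the forward oligonucleotide template from which
#' barcode libraries are cloned: 8 blocks of four random bases (`N`) each
#' followed by an invariant dinucleotide (CT, AC, TC, GT, TG, CA, AT, GC),
#' flanked by vector homology arms. Instantiating its `N` positions yields a
#' valid read body for the parser (see [instantiate_oligo()]).
#'
#' @format Character scalars.
#' @export
trace_anchor <- "TAGACAT"

#' @rdname trace_anchor
#' @export
trace_forward_oligo <- paste0(
  "CCTATAGTGAGTCGTATTAGAGACAT",
  "NNNNCTNNNNACNNNNTCNNNNGTNNNNTGNNNNCANNNNATNNNNGC",
  "ATCATCAAGATCGGAAGAGCGTCGTG"
)

#' Instantiate the N positions of a barcode oligo template
#'
#' Replaces every `N` with a uniformly random base, reproducing one synthesis
#' of the barcode oligo pool.
#'
#' @param oligo Template string (default [trace_forward_oligo]).
#' @return The instantiated sequence.
#' @examples
#' set.seed(1)
#' instantiate_oligo()
#' @export
instantiate_oligo <- function(oligo = trace_forward_oligo) {
  chars <- strsplit(oligo, "", fixed = TRUE)[[1]]
  n <- chars == "N"
  chars[n] <- sample(dna_bases, sum(n), replace = TRUE)
  paste(chars, collapse = "")
}

#' Extract the 48-bp clonal barcode region from reads
#'
#' Scans each read left to right for a 7-mer within Hamming distance 1 of the
#' `TAGACAT` anchor, trims the anchor and everything 5' of it, and takes the
#' next 48 bp. When `validate = TRUE` the extracted region must carry the
#' eight invariant dinucleotides at their fixed offsets (0-based 4, 10, ...,
#' 46); anchor candidates whose downstream region fails validation are passed
#' over and the scan continues, since the anchor motif can occur by chance
#' upstream of the true priming site.
#'
#' @param read_sequence Character vector of reads.
#' @param validate Check the invariant dinucleotides (default TRUE).
#' @param anchor Anchor sequence (7 bp).
#' @param max_mismatch Maximum Hamming mismatches in the anchor (default 1).
#' @return A tibble with columns `barcode48` (NA when rejected) and `status`
#'   (`"ok"`, `"no_anchor"`, `"truncated"` or `"invariant_mismatch"`).
#' @examples
#' extract_barcode_region(paste0("TAGACAT", strrep("ACGT", 12)))
#' @export
extract_barcode_region <- function(read_sequence, validate = TRUE,
                                   anchor = trace_anchor, max_mismatch = 1L) {
  n <- length(read_sequence)
  if (n == 0) {
    return(tibble(barcode48 = character(0), status = character(0)))
  }
  a <- strsplit(anchor, "", fixed = TRUE)[[1]]
  la <- length(a)
  len <- nchar(read_sequence)
  maxlen <- max(len)

  # character matrix of reads padded with a sentinel
  chars <- matrix("X", n, maxlen)
  split <- strsplit(read_sequence, "", fixed = TRUE)
  for (i in seq_len(n)) chars[i, seq_len(len[i])] <- split[[i]]

  barcode <- rep(NA_character_, n)
  resolved <- rep(FALSE, n)
  saw_candidate <- rep(FALSE, n)
  saw_invalid <- rep(FALSE, n)
  saw_short <- rep(FALSE, n)

  n_pos <- maxlen - la + 1L
  for (pos in seq_len(max(0L, n_pos))) {
    open <- which(!resolved & len >= pos + la - 1L)
    if (length(open) == 0) next
    mism <- integer(length(open))
    for (j in seq_len(la)) {
      mism <- mism + (chars[open, pos + j - 1L] != a[j])
    }
    cand <- open[mism <= max_mismatch]
    if (length(cand) == 0) next
    saw_candidate[cand] <- TRUE
    room <- len[cand] >= pos + la - 1L + barcode_length
    saw_short[cand[!room]] <- TRUE
    cand <- cand[room]
    if (length(cand) == 0) next
    bar <- substr(read_sequence[cand], pos + la, pos + la + barcode_length - 1L)
    if (validate) {
      valid <- validate_invariants(bar)
      saw_invalid[cand[!valid]] <- TRUE
      cand <- cand[valid]
      bar <- bar[valid]
    }
    barcode[cand] <- bar
    resolved[cand] <- TRUE
  }

  status <- rep("no_anchor", n)
  status[saw_candidate & saw_short] <- "truncated"
  status[saw_candidate & saw_invalid] <- "invariant_mismatch"
  status[resolved] <- "ok"
  tibble(barcode48 = barcode, status = status)
}

validate_invariants <- function(barcode48) {
  ok <- rep(TRUE, length(barcode48))
  for (k in seq_along(barcode_invariant_offsets)) {
    off <- barcode_invariant_offsets[k]
    ok <- ok & substr(barcode48, off + 1L, off + 2L) == barcode_invariant_dinucs[k]
  }
  ok
}

#' Parse clonal-barcode reads
#'
#' Applies [extract_barcode_region()] to a read table and additionally rejects
#' reads whose UMI consists only of G bases (a reverse-transcription artifact).
#'
#' @param reads Tibble with columns `cell_barcode`, `umi`, `read_sequence`.
#' @inheritParams extract_barcode_region
#' @return The input with `barcode48` and `status` columns appended; rows with
#'   `status == "ok"` carry a validated 48-mer. All-G UMIs get status
#'   `"umi_all_G"`.
#' @examples
#' reads <- tibble::tibble(
#'   cell_barcode = "c1", umi = "ACGTACGTAC",
#'   read_sequence = paste0("TAGACAT", strrep("ACGT", 12)))
#' parse_barcode_reads(reads)
#' @export
parse_barcode_reads <- function(reads, validate = TRUE,
                                anchor = trace_anchor, max_mismatch = 1L) {
  stopifnot(all(c("cell_barcode", "umi", "read_sequence") %in% names(reads)))
  parsed <- extract_barcode_region(reads$read_sequence, validate = validate,
                                   anchor = anchor, max_mismatch = max_mismatch)
  out <- bind_cols(as_tibble(reads), parsed)
  all_g <- grepl("^G+$", out$umi)
  out$status[all_g] <- "umi_all_G"
  out$barcode48[all_g] <- NA_character_
  out
}

#' Count cell-UMI-barcode triples and filter on read support
#'
#' Counts reads per (cell, UMI, barcode) triple and keeps triples supported by
#' at least `min_reads` reads, suppressing sequencing base-call errors.
#'
#' @param parsed Output of [parse_barcode_reads()] (only `status == "ok"` rows
#'   are used).
#' @param min_reads Minimum reads per triple (default 5; triples with fewer
#'   are removed).
#' @return Tibble `cell_barcode`, `umi`, `barcode48`, `read_count`.
#' @examples
#' parsed <- tibble::tibble(
#'   cell_barcode = "c1", umi = "AAAAAAAAAA",
#'   barcode48 = strrep("A", 48), status = "ok")
#' count_barcode_triples(parsed[rep(1, 5), ])
#' @export
count_barcode_triples <- function(parsed, min_reads = 5L) {
  parsed |>
    filter(.data$status == "ok") |>
    count(.data$cell_barcode, .data$umi, .data$barcode48,
          name = "read_count") |>
    filter(.data$read_count >= min_reads)
}

#' Call consensus clone barcodes by Levenshtein clustering
#'
#' Two-step edit-distance consensus clustering of observed 48-mers weighted by
#' read abundance. Step 1: every sequence is assigned to the most abundant
#' sequence within Levenshtein distance `d_assign` of it (the neighbourhood
#' includes the sequence itself, so isolated barcodes self-assign). Step 2:
#' the resulting assigned-to sequences are compared once more and any pair
#' within distance `d_collapse` is collapsed onto the more abundant member,
#' processing candidates in descending abundance so chains collapse to the
#' globally most abundant sequence. Abundance ties are broken by the
#' lexicographically smaller sequence throughout, making the result
#' deterministic and invariant to input order.
#'
#' @param barcode_counts Tibble with columns `barcode48` and `reads` (total
#'   read count per barcode), or a named numeric vector.
#' @param d_assign Step-1 neighbourhood radius (default 4).
#' @param d_collapse Step-2 collapse radius (default 2).
#' @return A list: `consensus` (character vector of clone barcodes) and `map`
#'   (tibble `barcode48` -> `consensus`).
#' @examples
#' call_clone_consensus(c(AAAA = 10, AAAT = 2))  # toy short barcodes
#' @export
call_clone_consensus <- function(barcode_counts, d_assign = 4L, d_collapse = 2L) {
  if (!is_tibble(barcode_counts) && !is.data.frame(barcode_counts)) {
    barcode_counts <- tibble(barcode48 = names(barcode_counts),
                             reads = as.numeric(barcode_counts))
  }
  stopifnot(all(c("barcode48", "reads") %in% names(barcode_counts)))
  ab <- barcode_counts |>
    group_by(.data$barcode48) |>
    summarise(reads = sum(.data$reads), .groups = "drop") |>
    arrange(desc(.data$reads), .data$barcode48)
  if (nrow(ab) == 0) abort("no barcodes to cluster.")

  seqs <- ab$barcode48
  reads <- ab$reads
  d <- adist(seqs)

  # Step 1: assign each sequence to the most abundant within d_assign.
  # seqs are sorted by (reads desc, lexicographic), so the first neighbour in
  # order is the most abundant with ties already broken.
  step1 <- vapply(seq_along(seqs), function(i) {
    nb <- which(d[i, ] <= d_assign)
    nb[1]
  }, integer(1))

  # Step 2: collapse candidate consensus sequences within d_collapse,
  # descending abundance.
  cand <- sort(unique(step1))  # indices, already in abundance order
  leader_of <- integer(length(seqs))
  leaders <- integer(0)
  for (i in cand) {
    if (length(leaders)) {
      d2 <- d[i, leaders]
      hit <- which(d2 <= d_collapse)
      if (length(hit)) {
        leader_of[i] <- leaders[hit[1]]  # most abundant qualifying leader
        next
      }
    }
    leaders <- c(leaders, i)
    leader_of[i] <- i
  }

  final <- leader_of[step1]
  list(
    consensus = seqs[leaders],
    map = tibble(barcode48 = seqs, consensus = seqs[final])
  )
}

#' Assign cells to clones and clones to samples
#'
#' Maps retained cell-UMI-barcode triples to consensus clones, assigns each
#' cell to the clone supported by the plurality of its UMIs (ties are left
#' unassigned), assigns each clone to the sample contributing most of its
#' cells, drops cells whose own sample disagrees with their clone's sample
#' (cross-sample transcript mixing during split-pooling), and removes clones
#' with fewer than `min_cells` remaining cells.
#'
#' @param triples Output of [count_barcode_triples()].
#' @param map Barcode-to-consensus map from [call_clone_consensus()] (the
#'   `map` tibble or the whole list).
#' @param cells Tibble with columns `cell` and `sample` (profiled, validated
#'   cells); extra columns are carried through.
#' @param min_cells Minimum cells per clone (default 5).
#' @return A list of class `"clone_assignment"`: `clones` (tibble `clone_id`,
#'   `consensus`, `sample`, `n_cells`), `cell_clones` (tibble `cell`,
#'   `clone_id`, `sample`, `n_umis`), `unassigned` (tibble `cell`, `reason`).
#' @export
assign_clones <- function(triples, map, cells, min_cells = 5L) {
  if (is.list(map) && !is.data.frame(map) && !is.null(map$map)) map <- map$map
  stopifnot(all(c("cell", "sample") %in% names(cells)))

  support <- triples |>
    inner_join(map, by = "barcode48") |>
    distinct(.data$cell_barcode, .data$umi, .data$consensus) |>
    count(.data$cell_barcode, .data$consensus, name = "n_umis") |>
    rename(cell = "cell_barcode") |>
    semi_join(cells, by = "cell")

  best <- support |>
    group_by(.data$cell) |>
    filter(.data$n_umis == max(.data$n_umis)) |>
    mutate(n_best = n()) |>
    ungroup()
  ambiguous <- best |> filter(.data$n_best > 1) |> distinct(.data$cell)
  cell_cons <- best |>
    filter(.data$n_best == 1) |>
    select("cell", "consensus", "n_umis") |>
    inner_join(select(cells, "cell", "sample"), by = "cell")

  # clone -> sample by plurality of member cells; ties to the smaller label
  clone_sample <- cell_cons |>
    count(.data$consensus, .data$sample, name = "n_cells") |>
    group_by(.data$consensus) |>
    arrange(desc(.data$n_cells), .data$sample, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("consensus", clone_sample = "sample")

  cell_cons <- cell_cons |> left_join(clone_sample, by = "consensus")
  cross <- cell_cons |> filter(.data$sample != .data$clone_sample)
  kept <- cell_cons |> filter(.data$sample == .data$clone_sample)

  sizes <- kept |> count(.data$consensus, name = "n_cells")
  small <- sizes |> filter(.data$n_cells < min_cells)
  kept_small <- kept |> semi_join(small, by = "consensus")
  kept <- kept |> anti_join(small, by = "consensus")

  clones <- kept |>
    count(.data$consensus, .data$clone_sample, name = "n_cells") |>
    arrange(desc(.data$n_cells), .data$consensus) |>
    mutate(clone_id = sprintf("clone_%03d", row_number())) |>
    select("clone_id", consensus = "consensus", sample = "clone_sample",
           "n_cells")

  cell_clones <- kept |>
    inner_join(select(clones, "clone_id", "consensus"), by = "consensus") |>
    select("cell", "clone_id", "sample", "n_umis") |>
    arrange(.data$cell)

  unassigned <- bind_rows(
    mutate(ambiguous, reason = "ambiguous"),
    transmute(cross, cell = .data$cell, reason = "cross_sample"),
    transmute(kept_small, cell = .data$cell, reason = "small_clone"),
    cells |>
      anti_join(support, by = "cell") |>
      transmute(cell = .data$cell, reason = "no_barcode")
  )

  structure(list(clones = clones, cell_clones = cell_clones,
                 unassigned = unassigned),
            class = "clone_assignment")
}

#' @exportS3Method base::print
print.clone_assignment <- function(x, ...) {
  cat("<clone_assignment> ", nrow(x$clones), " clones, ",
      nrow(x$cell_clones), " cells assigned, ",
      nrow(x$unassigned), " cells unassigned\n", sep = "")
  invisible(x)
}

#' Full clone-calling pipeline
#'
#' Convenience wrapper chaining [parse_barcode_reads()],
#' [count_barcode_triples()], [call_clone_consensus()] and [assign_clones()].
#'
#' @inheritParams parse_barcode_reads
#' @inheritParams count_barcode_triples
#' @inheritParams call_clone_consensus
#' @inheritParams assign_clones
#' @return A `"clone_assignment"` (see [assign_clones()]).
#' @export
call_clones <- function(reads, cells, min_reads = 5L, min_cells = 5L,
                        d_assign = 4L, d_collapse = 2L) {
  parsed <- parse_barcode_reads(reads)
  triples <- count_barcode_triples(parsed, min_reads = min_reads)
  if (nrow(triples) == 0) abort("no barcode triples survive the read filter.")
  counts <- triples |>
    group_by(.data$barcode48) |>
    summarise(reads = sum(.data$read_count), .groups = "drop")
  cons <- call_clone_consensus(counts, d_assign = d_assign,
                               d_collapse = d_collapse)
  assign_clones(triples, cons, cells, min_cells = min_cells)
}
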