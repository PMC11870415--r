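# clonmem

Tools for asking whether an epigenetic state is **clonally heritable**: when
tissue recovers from an injury such as colitis, do individual stem-cell clones
remember the insult — carrying elevated AP-1 motif accessibility and its
associated gene programs across cell divisions — and does that memory
predispose them to tumor formation?

`clonmem` implements the computational core of that question for
lineage-barcoded single-cell multiome (ATAC + RNA) experiments:

* **Clone calling** from expressed 48-bp DNA barcodes: anchor-based read
  parsing with invariant-dinucleotide validation, UMI/read-support filtering,
  and two-step Levenshtein consensus clustering
  (`parse_barcode_reads()`, `call_clone_consensus()`, `call_clones()`).
* **Background-matched deviation scores** for motif families and gene
  programs: for a feature set with weights *w*, the raw deviation of cell *i*
  is
  `Y_i = (Σ_f w_f x_if − Σ_f w_f e_if) / Σ_f w_f e_if`
  with `e_if = depth_i · total_f / grand_total`, z-scored against 250
  abundance-matched background feature sets (`deviation_scores()`), plus
  motif-family bagging, per-sample condition summaries, activated-cell
  fractions and downsampled KS tests.
* **The clonal-variance permutation test** — the package's central statistic.
  Per feature, the observed clonal variance is
  `median over clones( within-clone SD )²`; cell–clone labels are permuted
  (1000× by default) and
  `Z = (observed − mean_shuffled) / sd_shuffled`,
  `p = 2·pnorm(−|Z|)`, BH-adjusted. Heritable features have *low*
  within-clone variance, i.e. negative Z (`clonal_variance_test()`, with
  `tidy()`/`glance()`/`autoplot()` methods), plus clone-level condition
  comparisons and motif–program correlations across clones.
* **k-NN condition enrichment** in a latent embedding:
  `(observed % among k=100 neighbours) − (expected % = global condition
  fraction)` per cell (`knn_condition_enrichment()`).
* **Footprint memory and co-binding**: memory sites as footprint-score
  changes ≥ 0.2, peak-level co-occurrence odds ratios with 10th–90th
  percentile normalisation onto [−1, 1], midpoint distances to the nearest
  AP-1 site, and a sensitivity/specificity sweep of footprint change against
  independent differential-binding labels (`call_memory_sites()`,
  `cobinding_matrix()`, `footprint_performance_curve()`).
* **Spatial tumor scoring** on 16-µm binned spatial transcriptomics: depth
  QC, PC-space smoothing, Axin2 z ≥ 1 tumor-bin calls, Louvain segmentation
  of the spatial k-NN graph into individual tumors, and pseudobulk program
  scoring with the same deviation statistic (`qc_normalize_smooth()`,
  `call_tumor_bins()`, `segment_tumors()`, `score_tumors()`).
* A **synthetic-data generator** (`simulation_config()`,
  `simulate_multiome()`, `simulate_barcode_reads()`, `simulate_footprints()`,
  `simulate_spatial()`) that plants known clonal structure (tunable
  intraclass correlation), condition shifts, a high-memory clone
  subpopulation, barcode reads with per-base errors, footprint co-occurrence
  and Axin2-high tumors — so the whole pipeline is testable end to end with
  no external data.

All user-facing functions take data frames (or sparse `Matrix` counts) and
return tibbles, so analyses chain with the pipe.

## Worked example

Simulate four animals (two control, two recovered from injury) with ten
clones each, strong clonal heritability on the AP-1-like family
(ICC = 0.5) and weak heritability elsewhere (ICC = 0.1); call clones from
noisy barcode reads; score motif families; test heritability.

```r
library(clonmem)
library(dplyr)

cfg <- simulation_config(seed = 7, n_samples = 4, n_cells_per_sample = 300,
                         n_peaks = 1000, n_genes = 400, n_clones_per_sample = 10,
                         icc_per_family = c(0.5, rep(0.1, 7)),
                         barcode_error_rate = 0.01)
sim    <- simulate_multiome(cfg)
reads  <- simulate_barcode_reads(sim$clone_truth, cfg)
clones <- call_clones(reads$reads, sim$cells)
clones
#> <clone_assignment> 40 clones, 626 cells assigned, 574 cells unassigned

scores <- deviation_scores(sim$counts_peaks, sim$peak_annotation, seed = 1)
cvt    <- clonal_variance_test(scores, clones, n_perm = 500, seed = 1)
glance(cvt)
#> # A tibble: 1 × 5
#>   n_features n_clones n_cells n_perm n_heritable
#>        <int>    <int>   <int>  <dbl>       <int>
#> 1          8       40     626    500           2

tidy(cvt) |> arrange(z) |>
  select(feature, observed_clonal_variance, z, p_value, fdr) |> head(3)
#> # A tibble: 3 × 5
#>   feature   observed_clonal_variance      z  p_value      fdr
#>   <chr>                        <dbl>  <dbl>    <dbl>    <dbl>
#> 1 AP1                           5.65 -14.2  1.50e-45 1.20e-44
#> 2 HNF4_PPAR                     9.88  -3.99 6.47e- 5 2.59e- 4
#> 3 FOX                           9.33  -2.24 2.50e- 2 6.67e- 2
```

All 40 planted clones are recovered (cells without a surviving
barcode UMI after the ≥5-reads-per-triple filter stay unassigned). The
AP-1 family — planted with half of its latent variance between clones —
shows an observed clonal variance of 5.65 against a shuffled mean of ~15.6,
i.e. Z = −14.2: cells of a clone resemble each other far more than permuted
clones would, the signature of heritable memory. Families planted at
ICC = 0.1 sit near the significance boundary, as expected at this depth.

The fraction of "activated" cells (score > 1.5) per animal separates the
recovered animals from controls:

```r
activated_fraction(scores, sim$cells, "AP1")
#> # A tibble: 4 × 5
#>   sample condition n_cells n_activated fraction
#>   <chr>  <chr>       <int>       <int>    <dbl>
#> 1 S01    control       300          38    0.127
#> 2 S02    recovered     300         138    0.46
#> 3 S03    control       300          32    0.107
#> 4 S04    recovered     300         160    0.533
```

See the methods vignette (`vignettes/clonal-memory-methods.Rmd`) for the
model, parameter choices and limitations.

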