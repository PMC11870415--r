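---
title: "Methods: quantifying clonal epigenetic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying clonal epigenetic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonmem` asks whether single-cell epigenomic states are inherited through
cell division. The experimental design it serves combines three layers:
single-cell multiome profiles (ATAC + RNA), an expressed DNA barcode that
marks each founder clone, and — for the neoplasia endpoint — binned spatial
transcriptomics of tumor-bearing tissue. This vignette describes each
statistical component, the assumptions behind it, the tunable parameters,
and what the synthetic-data generator does and does not emulate.

## Clone calling from expressed barcodes

Barcode transcripts carry a fixed 7-bp anchor (`TAGACAT`) followed by a
48-bp variable region in which every block of four random bases is followed
by one of eight invariant dinucleotides (CT, AC, TC, GT, TG, CA, AT, GC at
0-based offsets 4, 10, ..., 46). Parsing proceeds per read:

1. scan left to right for a 7-mer within Hamming distance 1 of the anchor;
2. trim the anchor and everything 5' of it and take the next 48 bp;
3. reject reads whose UMI is all G (a template-switching artifact) and
   extractions whose invariant dinucleotides mismatch.

One deliberate refinement: when the 48-mer downstream of an anchor
candidate fails invariant validation, the scan *continues* to the next
candidate rather than rejecting the read. The anchor motif (or a 1-mismatch
neighbour of it — here `GAGACAT` inside the vector homology arm) can occur
by chance upstream of the true priming site, and the invariant check is
precisely the evidence that distinguishes the real barcode. A read
instantiated from the forward cloning oligo demonstrates the case: the
leftmost near-anchor sits in the vector arm, and only fall-through scanning
recovers the true variable region.

Reads are then aggregated per (cell, UMI, barcode) triple and triples with
fewer than 5 reads are discarded, suppressing base-call errors (a UMI's
surviving barcode must be read identically at least five times). Consensus
clones are called in two steps on the surviving 48-mers, weighted by read
abundance:

* **Step 1** — each sequence is assigned to the most abundant sequence
  within Levenshtein distance 4 of it (the neighbourhood includes the
  sequence itself, so isolated barcodes self-assign).
* **Step 2** — the resulting assigned-to set is compared once more and any
  pair within distance 2 collapses onto the more abundant member,
  processed in descending abundance so chains collapse to the globally most
  abundant sequence.

All abundance ties break toward the lexicographically smaller sequence,
which makes the clustering deterministic and invariant to input order.
Cells are assigned to the clone supported by the plurality of their UMIs;
cells tied between clones are recorded as unassigned rather than guessed.
Each clone is assigned to the sample contributing most of its cells, cells
contradicting their clone's sample are dropped (split-pool transcript
mixing), and clones with fewer than 5 remaining cells are removed.

With 1% per-base error and 5 reads per UMI, a UMI survives the triple
filter only when all five reads agree (probability ≈ 0.6^5 ≈ 0.09 per
barcode copy), so a minority of cells retain no barcode evidence at all;
they are reported as unassigned. Among assigned cells, recovery against
planted truth is essentially perfect because planted consensus barcodes are
kept at pairwise distance ≥ 9, twice the step-1 radius plus a margin.

## Background-matched deviation scores

Accessibility and expression counts are dominated by cell depth and feature
abundance. The deviation score removes both nuisances non-parametrically.
With counts `x`, the null expectation for cell *i* and feature *f* is
`e_if = depth_i · total_f / grand_total`. For a feature set (motif family
or gene program) with weights `w`:

```
Y_i      = (Σ_f w_f x_if − Σ_f w_f e_if) / Σ_f w_f e_if
score_i  = (Y_i − mean_b Y_i^(b)) / sd_b Y_i^(b)
```

where replicate *b* substitutes every weighted feature by its *b*-th
matched background feature, keeping the weight. Defaults are 250 background
replicates drawn from 20 equal-size bins of mean feature abundance;
backgrounds are sampled with replacement and never include the feature
itself. Sampling with replacement keeps the replicate count fixed even when
a bin is small. For peaks the binning variable is mean fragment count;
sequence-aware matching (e.g. GC) is intentionally out of scope — synthetic
peaks have no sequence — and users with their own matching can pass a
precomputed bin assignment.

Numerical conventions: when the background standard deviation is zero the
score is 0 if the raw deviation also equals the background mean (the
all-null case, e.g. counts exactly at expectation) and missing otherwise,
with a warning. The implementation accumulates background moments in a
running sum and matches a dense brute-force oracle to 1e-10 on small
matrices.

Motif families are built by greedy leader bagging: motifs sorted by
score variability across cells, each unmerged motif becomes a leader and
absorbs all unmerged motifs with similarity q-value < 0.05 to it. The
leader's annotation represents the family. Downstream summaries follow the
same conventions throughout: "activated" cells have score > 1.5 (strict);
per-sample condition changes are sample mean minus the mean of control
sample means; t-tests compare per-sample means with BH adjustment across
the 50 most variable families; heterogeneity tests downsample each
condition to 500 cells before a two-sample KS test.

## The clonal-variance permutation test

For each feature, within-clone standard deviations are computed across the
cells of every clone; the observed clonal variance is the median of these
SDs across clones, squared. Cell–clone labels are then permuted uniformly
across all clone-assigned cells (clone sizes preserved; a true permutation,
not a bootstrap), the statistic is recomputed 1000 times, and

```
Z = (observed − mean_shuffled) / sd_shuffled,  p = 2 · pnorm(−|Z|)
```

with BH adjustment across features. Heritable features give negative Z.
Choices worth stating:

* **Global permutation.** Shuffling spans samples, so a feature that is
  constant within samples but differs between them (e.g. anatomical
  position) registers as "clonal" — which is the behaviour that makes
  regional signatures visible in this test. An optional
  `stratify_by_sample = TRUE` removes that component.
* **Two-sided p-values** are reported even though heritability is
  one-sided; users can halve them for a directional test. The `glance()`
  summary counts features with FDR < 0.05 *and* Z < 0.
* Sample SD uses denominator n−1; both observed and shuffled statistics are
  squared before moments are taken (they are "clonal variance" quantities).
* Constant features have a degenerate null (sd 0); they are flagged and
  excluded from the FDR rather than given an arbitrary Z.
* The normal approximation to the permutation null is accurate at realistic
  clone counts: with 30 clones × 20 cells and 200 permutations, the
  fraction of null features at p < 0.05 lands inside the 95% binomial
  interval around 0.05 (checked over 1000 simulated null features), and
  with 4 cells in 2 clones the permuted statistic reproduces the exhaustive
  enumeration of label splits exactly. A subtlety of that smallest case:
  two of the three distinct splits always share the same median-of-SDs
  value, so the exact null has two support points with weights 1/3 and 2/3.

Clone-level comparisons between conditions operate on per-clone medians and
SDs: a KS test on the SDs, differences of median-of-medians and
median-of-SDs (condition minus control), and the fraction of "high" clones
(median score > 1.25). Motif–program coupling is the Pearson correlation of
clone-mean motif scores with clone-mean program scores across clones.

## k-NN condition enrichment

Within a latent embedding supplied by the user (topic space or PCs — the
embedding itself is out of scope), each cell's 100 nearest Euclidean
neighbours (self excluded, distance ties broken by cell index) are
classified by condition; enrichment is the observed neighbourhood fraction
minus the expected fraction, which under random assignment is simply each
condition's global share. Enrichment therefore sums to zero across
conditions for every cell, is bounded in [−1, 1], and is invariant to rigid
rotations of the embedding. Excluding the self avoids inflating
own-condition enrichment by 1/k.

## Footprint memory and co-binding

Footprint scores arrive as 10-bp-binned, quantile-transformed values in
[0, 1] per condition (sites with maximum score < 0.2 everywhere are assumed
pre-filtered upstream). A *memory footprint* changes by at least 0.2
between condition and control — inclusive, reading "minimum change of 0.2"
literally — with a `loss` mode for inhibitor experiments. For every family
pair, peaks are cross-classified (both / first only / second only /
neither) and the odds ratio `(both · neither) / (first · second)` is
log2-transformed, with the Haldane +0.5 correction applied to all four
cells whenever any is zero; the statistic is exactly symmetric in the pair.
Normalisation maps positive log2 ORs linearly between the 10th and 90th
percentiles (linear-interpolation quantiles, fixed for reproducibility) of
all positive values in the pooling set onto [0, 1], clipped, and negative
values analogously onto [−1, 0]. The pooling set is explicit — pool all
pairs and timepoints of one experiment by row-binding before normalising. A
degenerate percentile range maps to 0 with a warning rather than inventing
signal.

Distances between co-binding partners use bin midpoints
(`bin_start + 5` bp) within the same peak, reporting each non-reference
memory site's distance to the nearest AP-1 memory site and the fraction
closer than 20 bp ("adjacent"). The performance sweep collapses a family's
sites to one change per peak (largest |Δ|) and, against independent
differential-binding labels, reports sensitivity, specificity and accuracy
of `|Δ| ≥ t` over a threshold grid; sensitivity is monotonically
non-increasing and specificity non-decreasing in t by construction.

## Spatial tumor identification and scoring

Bins below 300 reads are dropped; remaining bins are scaled to the mean
depth, log2(x+1)-transformed, and smoothed by averaging each gene over the
k = 20 nearest bins in top-20-PC space (the bin itself counts as one of the
20). Tumor bins have smoothed Axin2 z-score ≥ 1 — inclusive, reading
"minimum value of 1" literally, while the high-AP-1 tumor threshold
"score > 1.5" is strict; a constant marker is defined to have z = 0
everywhere, so flat fields produce no calls. Called bins are segmented into
individual tumors by Louvain community detection on the symmetrised
k = 5 spatial nearest-neighbour graph, with a seeded RNG for determinism.

The Louvain resolution default is 0.1, not 1.0. At resolution 1.0
modularity optimisation splits even a single solid disc of ~50 bins into
several communities (an instance of modularity's resolution bias on dense
homogeneous graphs); at 0.1 a disc of radius ≤ 6 bins stays whole while
well-separated tumors — disconnected components of the graph — can never
merge at any resolution. Recovery was verified across seeds for 3 and 12
planted tumors of radius 4.

Tumor pseudobulks (summed member-bin counts) are scored with the same
deviation statistic, treating tumors as cells and the AP-1 program gene set
(top-150 program genes intersected with the probe set; an empty overlap is
an error) as a binary annotation with expression-binned background genes —
binned on pseudobulk means, the natural scale of the scored objects.

## The synthetic-data generator

The generator is the package's study design, not a convenience: its
defaults define the conditions under which the pipeline is validated.

* **Latent model.** Per cell and family,
  `s = clone_effect + condition_shift + cell_noise` with
  `Var(clone_effect) = ICC` and total latent variance 1. Non-control
  conditions add a mean shift (default +1 on the AP-1-like family only);
  a `high_memory_fraction` (default 0.1) of exposed-condition clones gains
  `delta_high` (default 2) on the memory families, creating the bimodal
  exposed-clone distribution the analysis is designed to detect.
* **Counts.** Cell depths are log-normal (default mean log 2000, sd 0.3);
  given a cell's rates — log-linear in the latent scores of annotating
  families — counts are multinomial at the sampled depth, i.e. Poisson
  given rates conditioned on the cell total, so count totals conserve the
  sampled depths exactly and the deviation-score null holds by
  construction.
* **Barcodes.** 30-ish planted consensus barcodes at pairwise Levenshtein
  distance ≥ 9; 8 UMIs per cell, 5 reads per UMI, i.i.d. substitution
  errors (default 0.005/base), optional junk reads (broken anchor or all-G
  UMI). One RNG stream per artifact, derived from the master seed by fixed
  offsets, so regenerating one artifact never perturbs another and
  identical configurations are bit-identical.
* **Footprints.** Memory deltas are drawn from U(0.25, 0.5) (all above the
  0.2 call threshold), null changes from U(−0.1, 0.1); per partner family
  the probability of sharing a peak with an AP-1 memory site is the
  configured co-occurrence while the partner's marginal rate is preserved,
  so co-occurrence = marginal rate is exact independence (log2 OR ≈ 0).
  Partner sites in shared peaks sit within one bin of the AP-1 site.
* **Spatial.** Non-overlapping discs (default radius 4 bins on a 48×48 grid
  of 16-µm bins) multiply the Axin2 rate by 8; half of the tumors also
  elevate the AP-1 program genes. A small fraction of bins is given
  sub-threshold depth to exercise QC.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: sequence content (GC bias, mappability),
doublets and clumps, batch effects, overdispersion beyond multinomial
sampling (a dispersion knob would be the natural extension), spatial
segmentation artifacts, and the cell-type heterogeneity that real tissue
adds on top of condition and clone. Results on real data additionally
depend on upstream peak calling, embedding quality and footprint-model
calibration, all of which are explicit inputs here.

## Problem sizes

The test suite validates at deliberately modest scales chosen to make the
statistical claims sharp rather than to mimic full-study size: clone
recovery at 30 clones × ~27 cells with 1% read error; permutation-test
calibration on 1000 null features at 30 clones × 20 cells with 200
permutations; oracle equivalence on ≤ 10 × 20 matrices; co-binding
independence at 2000 peaks; spatial recovery over 20 seeds each for 3
tumors (48×48 grid) and 12 tumors (64×64 grid). Published effect sizes from
full animal cohorts (hundreds of clones, hundreds of tumors) are not
reproducible at these scales and are not asserted.

## Known limitations

* `utils::adist` computes the full Levenshtein matrix; beyond ~10⁴ unique
  post-filter barcodes a banded or indexed edit-distance method would be
  needed.
* The k-NN search is exact and chunked; it is comfortable to ~10⁵ points
  but is not an approximate-NN index.
* The permutation test's normal tail approximation can misbehave when
  clones are very few (< ~10); the permutation null can be returned
  directly (`return_null = TRUE`) for exact inspection.
* Cells tied between clones are dropped, a conservative choice that loses
  a small amount of data rather than risking misassignment.
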