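---
title: "Quality assessment and benchmarking of imaging-based spatial transcriptomics with srtqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment and benchmarking of imaging-based spatial transcriptomics with srtqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtqc)
```

## Scope

Imaging-based spatially resolved transcriptomics (SRT) platforms such as
10x Genomics Xenium decode individual transcripts in tissue, reporting for
every read its 3D position in micrometers, gene identity and a phred-scaled
quality value (qv). Turning these reads into a trustworthy cell-by-gene
matrix involves quality filtering, cell segmentation, read assignment and
preprocessing, and each step can silently distort downstream cell typing.
`srtqc` implements a family of quantitative checks for this pipeline:

* baseline read/cell QC filters and summaries;
* two specificity metrics against an annotated scRNA-seq reference —
  negative marker purity (NMP) and negative co-expression purity (NCP);
* per-gene detection-efficiency ratios and centroid-distance read profiles;
* an optimal nuclear-expansion estimator;
* segmentation-output evaluation (mask expansion, read assignment,
  majority-vote typing, a background-intensity false-cell filter);
* a preprocessing-workflow benchmark with partition-similarity metrics,
  imputation metrics and control-probe false-positive rates;
* a kernel-density z-axis coherence score that detects cells stacked in z;
* a seeded simulator that generates Xenium-like matrices and spatial
  point-cloud fixtures with full ground truth, so every metric can be
  validated without external data.

## Data model

A `transcript_table` is a data.frame with one row per decoded read
(`x`, `y`, `z` in um, `gene`, `qv`, optional `cell_id` with `NA` for
unassigned reads, optional `overlaps_nucleus`). A `cell_gene_matrix` wraps
a sparse integer count matrix (cells x features) with per-cell metadata;
a `reference_profile` holds annotated single-cell counts whose per-type
mean-expression signatures are always recomputed from the counts. Counts
round-trip exactly through MatrixMarket plus TSV sidecars. All
coordinates are micrometers; pixel conversions use a configurable pixel
size (default 0.2125 um/px, the Xenium morphology-image resolution). All
spatial bins are half-open `[a, b)`.

Two conventions are deliberately strict:

* the qv filter keeps reads with `qv > qv_min` (strict, default 20);
* the cell filter keeps cells with at least `min_reads` total reads
  (default 10; "fewer than ten" are dropped).

## Negative marker purity (NMP)

A gene g is a *negative marker* for cell type c when fewer than 0.5% of
type-c cells in the reference express it (count > 0). Reads of such genes
observed in type-c cells of the spatial data indicate mis-assignment. To
remove the influence of cell-type abundance, per-type mean raw expression
is balanced per gene:

$$\bar X_{g,c}^{(m)} = \frac{\bar x_{g,c}^{(m)}}{\sum_{c'} \bar x_{g,c'}^{(m)}},$$

computed for both modalities (sp = spatial, sc = reference). The balanced
values over all negative pairs $P^{neg} = \{(g, c)\}$ are averaged into
$\bar X_{neg}^{(m)}$, and

$$\mathrm{NMP} = \begin{cases}
1 - \left(\bar X_{neg}^{(sp)} - \bar X_{neg}^{(sc)}\right) &
  \bar X_{neg}^{(sp)} > \bar X_{neg}^{(sc)} \\
1 & \text{otherwise.}
\end{cases}$$

Genes with zero total mean expression in either modality have no defined
balanced row and are dropped from $P^{neg}$ with a warning rather than
treated as 0/0. Because each negative marker contributes one term per
negative type, a marker is implicitly weighted by the size of its negative
type set.

`scaled_nmp()` re-anchors the score so that 0 corresponds to chance:
the baseline b is the mean raw NMP over `n_perm` (default 20) uniform
permutations of the spatial cell-type labels, and the scaled score is
`(raw - b) / (1 - b)` (1 maps to 1; values below the baseline are negative
and reported as-is). Each permutation draws its RNG stream from a
`(seed, index)`-derived sub-seed, so the baseline is independent of
evaluation order. The permutation is applied to the matrix under
evaluation by default; an external baseline matrix (e.g. a binning
segmentation of the same dataset) can be supplied instead.

## Negative co-expression purity (NCP)

Pairs of genes that are never co-expressed in single cells of the
reference should not co-occur within cells in situ; when they do, the
co-occurrence is evidence of non-specific signal or segmentation bleed.
A cell co-expresses a pair when both counts are positive. The paper-level
definition leaves the numeric cut open; we use the same 0.5% fraction
threshold on the co-expressing cell fraction on both sides (reference and
in-situ), configurable in both places. NCP is the fraction of evaluated
reference pairs that remain non-coexpressed in situ, in [0, 1], with 1 =
fully specific. Pairs whose genes are missing from the spatial panel are
dropped and counted.

NCP is sharp-edged: with dense matrices (many reads per cell relative to
panel size) even small uniform noise pushes almost every pair over the
0.5% cut at once, and the score collapses from 1 to 0 without an
intermediate regime. The metric is informative in the sparse,
nuclei-restricted regime it was designed for (tens of reads per cell over
a few hundred genes); the package's validation fixtures use such a regime
(8 types, 200 genes, ~20 reads/cell), where the score degrades smoothly
(about 1 → 0.85 → 0.14 at noise fractions 0, 0.1, 0.3).

## Detection efficiency

`gene_efficiency_ratio()` compares, per shared gene, the median
expression among *positive cells* between the spatial data and the
reference, reporting spatial/reference. "More than one read" is taken
literally (`positive_min = 2`, switchable to 1). Medians use the lower
median for even counts, so the statistic stays integer-valued and
bit-reproducible. Ratios are undefined (flagged `NA`) for genes with no
positive cells in either modality. Because medians of small integers are
coarse, the ratio only ranks genes reliably when panel genes are well
detected — one reason targeted panels are composed of strongly expressed
markers. `pseudobulk_area_ratio()` supports region-level comparisons
between platforms with different resolutions, normalising per-gene totals
by profiled area. `centroid_distance_profile()` reports the cumulative
proportion of assigned reads at distance >= d from their own cell
centroid (2D distance, ignoring z, matching the convention of
platform-comparison figures).

## Optimal nuclear expansion

Nuclear segmentation captures only part of a cell's reads; expanding
masks outward gains cytoplasmic signal until expansion starts swallowing
ambient tissue. The estimator works on three signature sets built from a
transcript table:

* *nuclear signatures*: per cell type, the normalised gene composition of
  nucleus-overlapping reads;
* *background signatures*: per tissue domain, the composition of reads
  not assigned to any cell;
* *distance-binned signatures*: every read — assigned or not — is
  attributed to its nearest cell centroid (within `max_dist`, default
  30 um) and binned by that distance into 1-um half-open intervals, per
  (cell type, domain).

Binning *all* reads by nearest-centroid distance is essential: bins beyond
the true cell boundary are populated by extracellular reads and converge
to the domain background, which is what the crossover detects. For each
(type, domain) pair with at least `min_reads` reads (default 5000;
lowered on desk-scale fixtures), each bin's composition is correlated
(Pearson, over all panel genes, zeros included, no transform) with the
type's nuclear signature and the domain's background signature. The
*optimal expansion* is the left edge of the smallest bin where the
background correlation exceeds the nuclear one; pairs that never cross
are flagged unbounded. Per-type values average over eligible domains.
`nuclear_edge_distance()` estimates the nuclear radius per cell as the
mean distance from the nuclear-read centroid to the convex hull vertices
of the nuclear reads (cells with fewer than three non-collinear reads are
skipped); the difference between mean crossover and mean nuclear radius
is the ideal expansion distance. On simulated disks the hull-vertex
estimate is biased a few percent low (hull vertices fall just inside the
true boundary) — well within the 10% recovery band used in validation.

## Segmentation evaluation

`expand_labels()` grows a label image into the background by an exact
Euclidean feature transform (the two-pass parabola-envelope algorithm,
implemented in C++), assigning contested pixels to the nearest label, so
expansions are Voronoi-constrained and never overlap; expansion is
monotone in distance. `assign_reads()` assigns each read the label under
its pixel (`inside`) or additionally the nearest label within `max_dist`
(`nearest`), with distances measured between pixel centres.
`majority_vote_types()` transfers a prior per-read annotation to new
cells by majority vote, breaking ties lexicographically so re-runs are
deterministic. `background_intensity_filter()` removes cells whose mean
stain intensity falls below `factor` (default 0.3) times the mean
background intensity of a surrounding window; the image is tiled into
non-overlapping `window`-sized tiles anchored at the origin (cells
evaluated in the tile holding their centroid) with a centred
`surround`-sized background window clipped at the image edge — the
simplest deterministic reading of a windowed filter. `seg_summary()`
gathers the ranking record: fraction of reads assigned, number of cells,
median and 5th-percentile reads and genes per cell (linear-interpolation
percentiles, R type 7), and raw plus scaled NMP.

## Preprocessing workflow benchmark

`run_workflow()` executes the fixed step order
normalization → log → HVF → scale → PCA → kNN graph → clustering, each
step optional. Normalizations: library-size to a target (10 / 100 / 1000 /
median), analytic negative-binomial Pearson residuals (theta = 100,
clipped at sqrt(n); the log step is forced off, as residuals are already
variance-stabilised), or none. "All principal components" is read as all
computed components capped at 50 — panels of a few hundred genes make
this near-exhaustive. The kNN graph (default 16 neighbors) is the union
of directed kNN edges; clustering is igraph Louvain or Leiden with an
explicit seed, and identical-seed runs are bit-identical.
`tune_resolution()` bisects the resolution in [1e-3, 10] (at most 25
evaluations) until the cluster count is within +/-2 of the reference type
count, tracking the best candidate since cluster count is not assumed
monotone. `compare_partitions()` computes ARI (permutation-model
adjusted), VI (nats), NMI (arithmetic-mean normalisation) and FMI from
the contingency table; `perturb_and_score()` re-runs a workflow with one
step modified and scores it against the base partition.
`imputation_metrics()` scores predictions per gene: PCC on raw vectors,
SSIM on min-max-scaled vectors (C1 = 0.01^2, C2 = 0.03^2, dynamic range
1, sample moments), RMSE on z-scored vectors and Jensen-Shannon
divergence on sum-1-normalised vectors (natural log, 0 log 0 = 0).
`control_probe_fpr()` exploits that control probes cannot be genuinely
spatially variable: the fraction of control probes a caller selects
estimates its false-positive rate.

## Z-axis coherence

Cells stacked in z blend two expression signatures into one xy location.
The detector is segmentation-free: a Gaussian KDE vector field of
expression (default 2.5 px/um, bandwidth 2.5 um) is built for the full
dataset; gene vectors sampled at local maxima of the field norm
(8-neighborhood; tied plateaus keep their first pixel in column-major
order) are reduced by PCA to the smallest number of components explaining
at least 80% of variance. Reads are then split into top and bottom halves
within 2-um xy bins by each bin's mean z (reads at exactly the mean go to
the bottom), both halves are re-estimated as fields, projected into the
latent space, and compared per pixel by cosine similarity. Pixels where
either half's expression norm is below 5 are low-confidence and excluded,
as are pixels with zero projected vectors (marking them invalid avoids
spurious overlap calls). Nuclei whose mean similarity over valid pixels
falls strictly below 0.2 are flagged as likely overlaps.

The KDE is computed as the exact (untruncated) kernel sum by default: the
validation contract requires 1e-6 relative agreement with the direct
double-loop sum across the whole field, which any fixed small truncation
radius would violate far from reads; a `truncate` argument (in bandwidth
units) is available for large fields where the approximation is
acceptable.

One caveat found during validation: when each z-layer carries several
distinct cell types, the 80%-variance latent space can merge signatures
and miss a minority of true overlaps. With one signature per layer
(orthogonal gene blocks) detection is essentially perfect; real data sits
between these extremes, so flagged fractions should be read as lower
bounds.

## The simulator

`simulate_reference()` draws an annotated negative-binomial reference:
each type owns a block of near-exclusive markers (own-type mean =
baseline x 20, leak mean 0.002 elsewhere — near-exclusivity is what makes
negative markers and non-coexpressed pairs exist, as in real references),
over a shared log-uniform baseline (default [2, 20] — the scale of
well-detected targeted-panel genes, where median-based efficiency ratios
are informative). Variance is mu + 0.3 mu^2 by default; dispersion 0
gives Poisson. `select_panel()` ranks genes per type by one-vs-rest
Wilcoxon rank-sum (normal approximation with tie correction; ties broken
by log fold change, then name) and unions the top 50 per type.

Three seeded corruption operators turn a reference into Xenium-like data:

* `apply_efficiency()` resamples each count as Poisson(e_g x count) —
  one rule that covers both thinning (e < 1) and amplification (e > 1,
  observed for some genes in situ);
* `add_nonspecific_noise()` adds Poisson(rho/(1-rho) x total) reads,
  cells chosen proportionally to library size and genes uniformly over
  the panel (control probes can take a separate rate), so the expected
  noise share of the output is rho;
* `simulate_missegmentation()` pairs a fraction f of cells with a random
  partner and moves Binomial(partner count, m) reads per gene into the
  contaminated cell, conserving totals.

`generate_spatial_fixture()` builds spatial point clouds with full ground
truth: cells are non-overlapping disks (radius R, concentric nucleus
radius r) on a jittered grid (clearance `gap`, infeasible packings fail
fast); nuclear reads draw from the type composition inside r, cytoplasmic
reads in [r, R), and extracellular background reads from per-domain
compositions outside all disks; qv is a two-component Gaussian mixture
(85% around 35, 15% around 12, floored at 0) so quality filters have
work to do; z is uniform, or two separated layers when `two_layer = TRUE`
— cells in a central strip then get a same-xy partner in the second layer
with a disjoint gene signature, emulating stacked cells. Label images for
cells and nuclei are emitted along with per-read domains and the full
generating truth.

What the simulator does *not* emulate: optical crowding, probe-specific
chemistry, segmentation-shape irregularity (cells are disks), spatially
correlated noise, and continuous gradients of composition. Passing tests
therefore demonstrate correctness of the metrics and expected qualitative
responses, not platform-level performance claims on real tissue.

## Problem sizes and numerical choices

Validation runs use desk-scale instances chosen to exercise every code
path while staying statistically stable: references of 2–8 types x
60–200 genes x 80–500 cells/type; spatial fixtures of 16–40 cells
(~17k reads) on ~130x130 um fields; coherence fields of ~330x330 px at
2.5 px/um. Expansion eligibility is lowered to 2000 reads per pair on
these fixtures (the 5000 default targets full datasets). All stochastic
steps take explicit seeds, use restorable RNG state, and derive
per-iteration sub-seeds from (seed, index) so results are independent of
evaluation order. Degenerate inputs (empty matrices, silent genes,
single-type references, collinear nuclear reads, all-background bins)
either produce flagged results or fail with informative errors, as
exercised in the test suite.
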