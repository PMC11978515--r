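# srtqc — quality assessment and benchmarking for imaging-based spatial transcriptomics

Imaging-based spatially resolved transcriptomics (SRT) platforms such as
10x Genomics Xenium decode individual transcripts in tissue: every read
carries a 3D position (µm), a gene identity and a phred-scaled quality
value (qv). Between the raw reads and a trustworthy cell-by-gene matrix
sit quality filtering, cell segmentation, read assignment and
preprocessing — and each step can silently corrupt downstream cell
typing. `srtqc` gives analysts and method developers quantitative
instruments for this pipeline, validated end-to-end on a built-in
simulator with full ground truth.

## What it computes

**Specificity against an scRNA-seq reference.** A gene *g* is a *negative
marker* for cell type *c* when < 0.5 % of type-*c* reference cells express
it. With cell-type-balanced mean expression
X̄<sub>g,c</sub><sup>(m)</sup> = x̄<sub>g,c</sub><sup>(m)</sup> / Σ<sub>c′</sub> x̄<sub>g,c′</sub><sup>(m)</sup>
averaged over all negative pairs into X̄<sub>neg</sub><sup>(m)</sup>,
the **negative marker purity** is

NMP = 1 − (X̄<sub>neg</sub><sup>(sp)</sup> − X̄<sub>neg</sub><sup>(sc)</sup>) when X̄<sub>neg</sub><sup>(sp)</sup> > X̄<sub>neg</sub><sup>(sc)</sup>, else 1,

optionally rescaled so that 0 equals the mean NMP of 20 label
permutations. The **negative co-expression purity** (NCP) is the fraction
of gene pairs non-coexpressed in the reference that stay non-coexpressed
in situ. Both scores reach 1 for perfectly specific data and fall with
mis-segmentation (NMP) or non-specific signal (NCP).

**Detection efficiency.** Per-gene ratio of median expression among
positive cells (spatial / reference), area-normalised pseudobulk ratios,
and cumulative centroid-distance read profiles.

**Optimal nuclear expansion.** Distance-binned gene compositions (1-µm
bins, every read attributed to its nearest cell centroid) are correlated
against nuclear and domain-background signatures; the crossover distance
where background wins is the optimal expansion, and the nuclear radius is
estimated from convex hulls of nuclear reads.

**Segmentation evaluation.** Voronoi-constrained mask expansion (exact
Euclidean feature transform in C++), inside/nearest read assignment,
majority-vote cell typing, a background-intensity false-cell filter, and
the summary record used to rank segmentation strategies (reads assigned,
cells, median/p5 reads and genes per cell, raw and scaled NMP).

**Preprocessing benchmark.** Configurable workflows (normalization → log
→ HVF → scale → PCA → kNN → Louvain/Leiden) with cluster-count-matched
resolution tuning, ARI/VI/NMI/FMI partition comparison, one-step-at-a-time
perturbation scoring, per-gene imputation metrics (PCC/SSIM/RMSE/JS) with
k-fold gene splits, and control-probe false-positive rates for spatially
variable feature callers.

**Z-axis coherence.** Gaussian-KDE expression fields (2.5 px/µm,
bandwidth 2.5 µm) for the top and bottom tissue halves are compared by
cosine similarity in a PCA latent space; nuclei with mean similarity
< 0.2 are flagged as two cells stacked in z.

**Simulator.** Annotated negative-binomial references, top-DE panel
selection, Poisson efficiency resampling, library-proportional uniform
noise, cross-cell contamination, and spatial disk-cell fixtures (nuclei,
cytoplasm, domain background, two z-layers, qv mixture) with complete
ground truth.

## Worked example

```r
library(srtqc)

# a seeded spatial fixture: 40 disk cells, 2 cell types, ambient background
fx <- generate_spatial_fixture(sim_config(n_cells = 40, n_types = 2, seed = 1))
tt <- fx$transcripts

# baseline QC: qv > 20 read filter, >= 10 reads/cell filter
m  <- filter_cells(build_cell_gene_matrix(filter_transcripts(tt, 20)), 10)
dataset_summary(tt, m, qv_min = 20)
#> QC summary
#>   cells:                40
#>   reads:                16713
#>   reads assigned:       76.6%
#>   reads with qv > 20:   85.3%
#>   mean reads/cell:      320.0 (qv-filtered 272.4)
#>   median genes/cell:    10.0 (qv-filtered 10.0)

# specificity of a deliberately mis-segmented matrix
ref <- simulate_reference(n_types = 4, n_genes = 80, cells_per_type = 150,
                          n_markers = 10, seed = 2)
mk  <- find_negative_markers(ref)            # (gene, type) negative pairs
sp  <- cell_gene_matrix(as.matrix(ref$counts),
                        data.frame(cell_id = rownames(ref$counts),
                                   cell_type = ref$cell_type))
bad <- simulate_missegmentation(sp, f = 0.3, mix = 0.25, seed = 3)$m
res <- scaled_nmp(bad, ref, mk, n_perm = 20, seed = 0)
sprintf("raw NMP %.3f, permutation baseline %.3f, scaled NMP %.3f",
        res$raw, res$baseline, res$scaled)
#> "raw NMP 0.983, permutation baseline 0.748, scaled NMP 0.932"
```

Contaminating 30 % of cells with a quarter of a random partner's reads
moves the raw NMP from 1 to 0.983; on the permutation-rescaled axis
(0 = chance labelling, 1 = perfectly pure) the same data scores 0.932.

A thin command-line front end is installed with the package
(`inst/scripts/srtqc`): `srtqc qc --transcripts T.csv --qv-min 20
--min-reads 10 --out summary.json`, plus `nmp`, `ncp` and `simulate`
subcommands.

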