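# lower-median convention: for even n the lower of the two middle order
# statistics, so medians of integer counts stay integer and reproducible
median_lower <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sort(x)[ceiling(n / 2)]
}

#' Per-gene detection-efficiency ratio against an scRNA-seq reference
#'
#' For each gene shared between the spatial panel and the reference: (1)
#' identify positive cells (cells with at least `positive_min` reads of the
#' gene), (2) take the median expression among positive cells in each
#' modality, (3) report the ratio spatial median / reference median. Values
#' above 1 mean the gene is detected more efficiently in situ than in the
#' reference.
#'
#' "Positive" is read literally as more than one read (`positive_min = 2`);
#' set `positive_min = 1` for the inclusive convention. Medians use the
#' lower-median convention for even counts so results are bit-reproducible.
#'
#' @param srt a [cell_gene_matrix()] or counts matrix (cells x genes).
#' @param sc a [reference_profile()] or counts matrix.
#' @param positive_min minimum count for a cell to count as positive.
#' @return data.frame with one row per common gene: `gene`, `median_srt`,
#'   `median_sc`, `ratio`, `n_pos_srt`, `n_pos_sc`. Genes with no positive
#'   cells in either modality have `NA` medians/ratio.
#' @export
gene_efficiency_ratio <- function(srt, sc, positive_min = 2) {
  a <- if (inherits(srt, "cell_gene_matrix")) srt$counts else srt
  b <- if (inherits(sc, "reference_profile")) sc$counts else sc
  genes <- intersect(colnames(a), colnames(b))
  if (length(genes) == 0) stop("no genes shared between spatial panel and reference")
  one <- function(m, g) {
    v <- m[, g]
    v <- v[v >= positive_min]
    c(median = median_lower(as.numeric(v)), n = length(v))
  }
  res <- lapply(genes, function(g) {
    sa <- one(a, g); sb <- one(b, g)
    data.frame(gene = g,
               median_srt = unname(sa["median"]),
               median_sc = unname(sb["median"]),
               ratio = unname(sa["median"] / sb["median"]),
               n_pos_srt = unname(sa["n"]),
               n_pos_sc = unname(sb["n"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Area-normalised pseudobulk ratio between two datasets
#'
#' Normalises per-gene total counts by the profiled area and reports, per
#' common gene, the ratio of densities a / b plus the median over genes with
#' a finite ratio. Genes detected in `a` but absent from `b` yield infinite
#' ratios and are reported separately.
#'
#' @param counts_a,counts_b named numeric vectors of per-gene total counts.
#' @param area_a,area_b profiled area (same units, e.g. um^2), > 0.
#' @return a list: `per_gene` (data.frame `gene`, `density_a`, `density_b`,
#'   `ratio`), `median_ratio` (over finite ratios), `n_infinite`.
#' @export
pseudobulk_area_ratio <- function(counts_a, area_a, counts_b, area_b) {
  if (area_a <= 0 || area_b <= 0) stop("areas must be positive")
  genes <- intersect(names(counts_a), names(counts_b))
  if (length(genes) == 0) stop("no common genes")
  da <- counts_a[genes] / area_a
  db <- counts_b[genes] / area_b
  ratio <- ifelse(db > 0, da / db, ifelse(da > 0, Inf, NA_real_))
  per_gene <- data.frame(gene = genes, density_a = unname(da),
                         density_b = unname(db), ratio = unname(ratio),
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       median_ratio = median(ratio[is.finite(ratio)]),
       n_infinite = sum(is.infinite(ratio)))
}

#' Cumulative proportion of reads by distance from the cell centroid
#'
#' For each distance `d` in `bins`, the proportion of assigned reads lying
#' at 2D Euclidean distance >= `d` from their own cell's centroid. The
#' profile starts at 1 for `d = 0` and is non-increasing; platforms whose
#' chemistry diffuses reads away from the cell body show heavier tails.
#'
#' @param t a [transcript_table()] with assigned reads.
#' @param centroids data.frame with `cell_id`, `x`, `y` (um); every assigned
#'   read's cell must appear.
#' @param bins numeric vector of distance edges (um).
#' @return data.frame `distance`, `prop_at_least` (proportion of assigned
#'   reads at distance >= the edge).
#' @export
centroid_distance_profile <- function(t, centroids, bins = 0:30) {
  a <- t[!is.na(t$cell_id), , drop = FALSE]
  if (nrow(a) == 0) stop("no assigned reads")
  idx <- match(a$cell_id, centroids$cell_id)
  if (anyNA(idx)) stop("centroid missing for some assigned cells")
  d <- sqrt((a$x - centroids$x[idx])^2 + (a$y - centroids$y[idx])^2)
  data.frame(
    distance = bins,
    prop_at_least = vapply(bins, function(b) mean(d >= b), numeric(1))
  )
}
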