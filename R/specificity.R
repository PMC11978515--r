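#' Identify negative markers from a single-cell reference
#'
#' A gene is a negative marker for a cell type when fewer than
#' `max_expressing_fraction` of that type's cells express it (count > 0) in
#' the reference. The default threshold of 0.5% follows the convention used
#' to define "negative cell types" for the NMP metric.
#'
#' @param ref a [reference_profile()] with at least two cell types.
#' @param max_expressing_fraction expressing-cell fraction below which the
#'   (gene, type) pair is a negative-marker pair.
#' @return a list of class `negative_marker_set`: `pairs` (data.frame with
#'   `gene`, `cell_type`), `neg_types` (named list, per gene, of its
#'   negative types), `genes`, `types`, and the threshold used.
#' @export
find_negative_markers <- function(ref, max_expressing_fraction = 0.005) {
  types <- sort(unique(ref$cell_type))
  if (length(types) < 2) {
    stop("need at least two cell types to define negative markers")
  }
  genes <- colnames(ref$counts)
  # expressing-cell fraction per (gene, type)
  frac <- vapply(types, function(ty) {
    sub <- ref$counts[ref$cell_type == ty, , drop = FALSE]
    Matrix::colSums(sub > 0) / nrow(sub)
  }, numeric(length(genes)))
  dimnames(frac) <- list(genes, types)
  hit <- which(frac < max_expressing_fraction, arr.ind = TRUE)
  pairs <- data.frame(gene = genes[hit[, 1]], cell_type = types[hit[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene, pairs$cell_type), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    neg_types = split(pairs$cell_type, factor(pairs$gene, levels = genes)),
    genes = genes, types = types,
    max_expressing_fraction = max_expressing_fraction
  ), class = "negative_marker_set")
}

#' Cell-type-balanced mean expression
#'
#' For each gene, the per-type mean raw expression is normalised by the sum
#' of the per-type means over all types, removing the influence of cell-type
#' proportions. Rows (genes) with zero total mean expression cannot be
#' normalised and are flagged undefined.
#'
#' @param counts cells x genes count matrix (dense or sparse, with
#'   dimnames), or a [cell_gene_matrix()] whose `cell_meta$cell_type` is
#'   set.
#' @param cell_type label per cell (ignored when `counts` is a
#'   `cell_gene_matrix` carrying labels).
#' @return a list of class `balanced_expression`: `xbar` (genes x types mean
#'   raw expression), `Xbar` (balanced, rows sum to 1), `undefined` (genes
#'   with zero total mean).
#' @export
balanced_expression <- function(counts, cell_type = NULL) {
  if (inherits(counts, "cell_gene_matrix")) {
    cell_type <- cell_type %||% counts$cell_meta$cell_type
    counts <- counts$counts
  }
  if (is.null(cell_type) || anyNA(cell_type)) {
    stop("every cell must carry a cell_type label")
  }
  cell_type <- as.character(cell_type)
  types <- sort(unique(cell_type))
  xbar <- vapply(types, function(ty) {
    n <- sum(cell_type == ty)
    if (n == 0) stop("empty cell type: ", ty)
    Matrix::colSums(counts[cell_type == ty, , drop = FALSE]) / n
  }, numeric(ncol(counts)))
  dimnames(xbar) <- list(colnames(counts), types)
  tot <- rowSums(xbar)
  Xbar <- xbar / ifelse(tot > 0, tot, NA_real_)
  structure(list(xbar = xbar, Xbar = Xbar,
                 undefined = colnames(counts)[tot == 0]),
            class = "balanced_expression")
}

# balanced negative-marker expression X̄_neg for one modality: the mean of
# the balanced expression over all (gene, negative type) pairs
balanced_negative_expression <- function(Xbar, pairs) {
  idx <- cbind(match(pairs$gene, rownames(Xbar)),
               match(pairs$cell_type, colnames(Xbar)))
  sum(Xbar[idx]) / nrow(pairs)
}

#' Negative marker purity (NMP)
#'
#' Measures how much expression of negative markers leaks into cell types
#' that should not express them, relative to an scRNA-seq reference. For
#' each modality m the cell-type-balanced expression of every negative
#' (gene, type) pair is averaged into X_neg^(m); the score is
#' `1 - (X_neg^(sp) - X_neg^(sc))` when the spatial aggregate exceeds the
#' reference aggregate and 1 otherwise, so 1 means no excess leakage.
#'
#' Pairs whose gene is missing from the spatial panel, or whose gene has
#' zero total mean expression in either modality (balanced expression
#' undefined), are dropped with a warning.
#'
#' @param sp a [cell_gene_matrix()] whose `cell_meta$cell_type` holds labels
#'   drawn from the reference's label set, or a plain counts matrix (then
#'   supply `sp_cell_type`).
#' @param ref a [reference_profile()].
#' @param markers a [find_negative_markers()] result derived from `ref`.
#' @param sp_cell_type optional label vector overriding the metadata.
#' @return a list of class `nmp_result`: `nmp`, `x_neg_sp`, `x_neg_sc`,
#'   `n_pairs` (pairs actually evaluated).
#' @export
negative_marker_purity <- function(sp, ref, markers, sp_cell_type = NULL) {
  if (inherits(sp, "cell_gene_matrix")) {
    sp_cell_type <- sp_cell_type %||% sp$cell_meta$cell_type
    sp_counts <- sp$counts
  } else {
    sp_counts <- sp
  }
  pairs <- markers$pairs
  if (nrow(pairs) == 0) stop("no negative markers under threshold")
  keep <- pairs$gene %in% colnames(sp_counts)
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no negative-marker genes present in the spatial panel")

  be_sp <- balanced_expression(sp_counts, sp_cell_type)
  be_sc <- balanced_expression(ref$counts, ref$cell_type)
  undef <- union(be_sp$undefined, intersect(be_sc$undefined, pairs$gene))
  if (any(pairs$gene %in% undef)) {
    warning("dropping ", sum(pairs$gene %in% undef),
            " negative-marker pair(s) with zero total mean expression")
    pairs <- pairs[!pairs$gene %in% undef, , drop = FALSE]
  }
  # spatial labels may cover only a subset of reference types; pairs whose
  # negative type is absent from the spatial labels cannot leak there
  pairs <- pairs[pairs$cell_type %in% colnames(be_sp$Xbar), , drop = FALSE]
  if (nrow(pairs) == 0) stop("no evaluable negative-marker pairs")

  x_sp <- balanced_negative_expression(be_sp$Xbar, pairs)
  x_sc <- balanced_negative_expression(be_sc$Xbar, pairs)
  nmp <- if (x_sp > x_sc) 1 - (x_sp - x_sc) else 1
  structure(list(nmp = nmp, x_neg_sp = x_sp, x_neg_sc = x_sc,
                 n_pairs = nrow(pairs)),
            class = "nmp_result")
}

#' Permutation-rescaled NMP
#'
#' Rescales the raw NMP so that 0 corresponds to the mean NMP obtained under
#' random permutations of the spatial cell-type labels while 1 remains the
#' maximum: `scaled = (raw - b) / (1 - b)` with `b` the permutation
#' baseline. Values below the baseline are negative and reported as-is.
#'
#' Each permutation uses an RNG stream derived from `(seed, index)`, so the
#' baseline does not depend on evaluation order.
#'
#' @inheritParams negative_marker_purity
#' @param n_perm number of label permutations for the baseline.
#' @param seed integer seed for the permutation streams.
#' @param baseline_sp optional [cell_gene_matrix()] whose labels are
#'   permuted instead of `sp`'s (e.g. a binning segmentation of the same
#'   dataset); defaults to `sp` itself.
#' @return a list of class `scaled_nmp_result`: `scaled`, `raw`,
#'   `baseline`, `n_perm`, plus the fields of the raw result.
#' @export
scaled_nmp <- function(sp, ref, markers, n_perm = 20, seed = 0,
                       sp_cell_type = NULL, baseline_sp = NULL) {
  stopifnot(n_perm >= 1)
  raw <- negative_marker_purity(sp, ref, markers, sp_cell_type = sp_cell_type)
  base_m <- baseline_sp %||% sp
  if (inherits(base_m, "cell_gene_matrix")) {
    base_counts <- base_m$counts
    base_labels <- base_m$cell_meta$cell_type
  } else {
    base_counts <- base_m
    base_labels <- sp_cell_type
  }
  perms <- vapply(seq_len(n_perm), function(i) {
    perm <- with_seed(derive_seed(seed, i), sample(base_labels))
    suppressWarnings(
      negative_marker_purity(base_counts, ref, markers,
                             sp_cell_type = perm)$nmp
    )
  }, numeric(1))
  b <- mean(perms)
  scaled <- if (b >= 1) 1 else (raw$nmp - b) / (1 - b)
  structure(list(scaled = scaled, raw = raw$nmp, baseline = b,
                 n_perm = n_perm, x_neg_sp = raw$x_neg_sp,
                 x_neg_sc = raw$x_neg_sc, n_pairs = raw$n_pairs),
            class = "scaled_nmp_result")
}

#' Identify non-coexpressed gene pairs in a reference
#'
#' A cell co-expresses a pair when both genes have count > 0 in that cell; a
#' pair is non-coexpressed when the co-expressing cell fraction is below
#' `coexpr_fraction_max`. The default threshold mirrors the negative-marker
#' expressing-fraction threshold (0.5%).
#'
#' @param ref a [reference_profile()] (or plain counts matrix) with at least
#'   two genes.
#' @param coexpr_fraction_max co-expressing cell fraction below which a pair
#'   counts as non-coexpressed.
#' @return a list of class `noncoexpressed_pairs`: `pairs` (data.frame
#'   `gene1`, `gene2`, unordered unique pairs with `gene1 < gene2`), and the
#'   threshold used.
#' @export
find_noncoexpressed_pairs <- function(ref, coexpr_fraction_max = 0.005) {
  counts <- if (inherits(ref, "reference_profile")) ref$counts else ref
  if (ncol(counts) < 2) stop("need at least two genes")
  pos <- counts > 0
  co <- as.matrix(Matrix::crossprod(pos * 1)) / nrow(counts)
  hit <- which(upper.tri(co) & co < coexpr_fraction_max, arr.ind = TRUE)
  pairs <- data.frame(gene1 = colnames(counts)[hit[, 1]],
                      gene2 = colnames(counts)[hit[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene1, pairs$gene2), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, coexpr_fraction_max = coexpr_fraction_max),
            class = "noncoexpressed_pairs")
}

#' Negative co-expression purity (NCP)
#'
#' The fraction of gene pairs non-coexpressed in the reference that remain
#' non-coexpressed in situ. A score near 1 indicates high specificity (pairs
#' that should not co-occur in a cell indeed do not); a score near 0
#' indicates widespread spurious co-expression.
#'
#' @param sp a [cell_gene_matrix()] or counts matrix.
#' @param pairs a [find_noncoexpressed_pairs()] result; pairs with a gene
#'   absent from the spatial panel are dropped and counted.
#' @param coexpr_fraction_max in-situ co-expressing cell fraction below
#'   which a pair still counts as non-coexpressed; defaults to the threshold
#'   stored in `pairs`.
#' @return a list of class `ncp_result`: `ncp`, `n_pairs` (evaluated),
#'   `n_dropped` (pairs with genes absent from the panel).
#' @export
ncp <- function(sp, pairs, coexpr_fraction_max = NULL) {
  counts <- if (inherits(sp, "cell_gene_matrix")) sp$counts else sp
  thr <- coexpr_fraction_max %||% pairs$coexpr_fraction_max
  pp <- pairs$pairs
  present <- pp$gene1 %in% colnames(counts) & pp$gene2 %in% colnames(counts)
  n_dropped <- sum(!present)
  pp <- pp[present, , drop = FALSE]
  if (nrow(pp) == 0) stop("no evaluable pairs: no pair has both genes in the panel")
  pos <- counts > 0
  co <- as.matrix(Matrix::crossprod(pos * 1)) / nrow(counts)
  frac <- co[cbind(match(pp$gene1, colnames(counts)),
                   match(pp$gene2, colnames(counts)))]
  structure(list(ncp = mean(frac < thr), n_pairs = nrow(pp),
                 n_dropped = n_dropped, coexpr_fraction_max = thr),
            class = "ncp_result")
}
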