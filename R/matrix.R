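#' Gene panels
#'
#' A panel is the ordered set of features targeted by an assay, with control
#' probes (decoy features with no biological target) flagged. Control probes
#' are recognised by configurable name prefixes following the Xenium export
#' convention.
#'
#' @param features character vector of unique feature identifiers.
#' @param control_prefixes name prefixes marking control probes.
#' @param is_control optional explicit logical flag per feature; overrides
#'   prefix matching.
#' @return a list of class `srt_panel` with `features` and `is_control`.
#' @export
make_panel <- function(features,
                       control_prefixes = c("NegControlProbe_",
                                            "NegControlCodeword_",
                                            "BLANK_", "antisense_"),
                       is_control = NULL) {
  features <- as.character(features)
  if (anyDuplicated(features)) stop("panel features must be unique")
  if (is.null(is_control)) {
    pat <- paste0("^(", paste(control_prefixes, collapse = "|"), ")")
    is_control <- grepl(pat, features)
  }
  stopifnot(length(is_control) == length(features))
  structure(list(features = features, is_control = is_control),
            class = "srt_panel")
}

#' Cell-by-gene count matrices
#'
#' Wraps a sparse nonnegative integer count matrix (cells in rows, features
#' in columns) together with per-cell metadata (centroid, optional cell type
#' label, optional area).
#'
#' @param counts a matrix or `Matrix::sparseMatrix` of nonnegative integer
#'   counts with unique row (cell) and column (feature) names.
#' @param cell_meta data.frame keyed 1:1 to the rows of `counts`; may carry
#'   `x`, `y` (centroid, um), `cell_type`, `area`.
#' @return a list of class `cell_gene_matrix`.
#' @export
cell_gene_matrix <- function(counts, cell_meta = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (methods::is(counts, "nMatrix")) {  # pattern matrix (e.g. empty .mtx)
    counts <- methods::as(counts, "dMatrix")
  }
  counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                        "generalMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be nonnegative integers")
  }
  if ((is.null(rownames(counts)) && nrow(counts) > 0) ||
      is.null(colnames(counts))) {
    stop("counts must carry cell (row) and feature (column) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("cell and feature identifiers must be unique")
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = rownames(counts) %||% character(0),
                            stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta)) {
    cell_meta$cell_id <- rownames(counts) %||% character(0)
  }
  rn <- rownames(counts) %||% character(0)
  if (!identical(as.character(cell_meta$cell_id), rn)) {
    stop("cell_meta must be keyed 1:1 to count rows, in order")
  }
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_gene_matrix")
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("cell_gene_matrix: %d cells x %d features, %d total counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Build a cell-by-gene matrix from a transcript table
#'
#' Tallies assigned reads into an integer count matrix; unassigned reads are
#' excluded. The per-cell centroid is the mean (x, y) of the cell's reads.
#'
#' @param t a [transcript_table()], nonempty.
#' @param panel a [make_panel()] giving the feature universe and order. If
#'   `NULL`, the sorted unique genes of `t` are used.
#' @return a [cell_gene_matrix()]; the grand total of counts equals the
#'   number of assigned reads.
#' @export
build_cell_gene_matrix <- function(t, panel = NULL) {
  stopifnot(nrow(t) > 0)
  if (is.null(panel)) panel <- make_panel(sort(unique(t$gene)))
  unknown <- setdiff(unique(t$gene), panel$features)
  if (length(unknown) > 0) {
    stop("features absent from panel: ", paste(unknown, collapse = ", "))
  }
  a <- t[!is.na(t$cell_id), , drop = FALSE]
  cells <- sort(unique(a$cell_id))
  counts <- Matrix::sparseMatrix(
    i = match(a$cell_id, cells),
    j = match(a$gene, panel$features),
    x = 1,
    dims = c(length(cells), length(panel$features)),
    dimnames = list(cells, panel$features)
  )
  cx <- vapply(split(a$x, factor(a$cell_id, levels = cells)), mean, numeric(1))
  cy <- vapply(split(a$y, factor(a$cell_id, levels = cells)), mean, numeric(1))
  cell_gene_matrix(counts, data.frame(cell_id = cells, x = cx, y = cy,
                                      stringsAsFactors = FALSE))
}

#' Remove cells with too few assigned reads
#'
#' Keeps cells whose total read count is at least `min_reads`; the Xenium
#' convention excludes cells with fewer than ten assigned reads. Metadata
#' rows are removed in lockstep.
#'
#' @param m a [cell_gene_matrix()].
#' @param min_reads minimum total reads for a cell to be retained.
#' @return the filtered [cell_gene_matrix()].
#' @export
filter_cells <- function(m, min_reads = 10) {
  stopifnot(min_reads >= 0)
  keep <- Matrix::rowSums(m$counts) >= min_reads
  cell_gene_matrix(m$counts[keep, , drop = FALSE],
                   m$cell_meta[keep, , drop = FALSE])
}

#' Annotated single-cell reference profiles
#'
#' Holds an annotated scRNA-seq count matrix plus the per-type mean raw
#' expression signatures derived from it. The mean-expression matrix is
#' always recomputed from the counts, so the two can never drift apart.
#'
#' @param counts cells x genes nonnegative integer matrix with dimnames.
#' @param cell_type character/factor label per cell; every type must have at
#'   least one cell.
#' @return a list of class `reference_profile` with `counts`, `cell_type`
#'   and `mean_expr` (genes x types mean raw expression).
#' @export
reference_profile <- function(counts, cell_type) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(counts) == length(cell_type))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("reference counts must carry dimnames")
  }
  cell_type <- as.character(cell_type)
  if (anyNA(cell_type)) stop("every reference cell must be labeled")
  types <- sort(unique(cell_type))
  mean_expr <- vapply(types, function(ty) {
    Matrix::colSums(counts[cell_type == ty, , drop = FALSE]) /
      sum(cell_type == ty)
  }, numeric(ncol(counts)))
  dimnames(mean_expr) <- list(colnames(counts), types)
  structure(list(counts = counts, cell_type = cell_type,
                 mean_expr = mean_expr),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile: %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_type))))
  invisible(x)
}

#' Read and write counts as MatrixMarket with TSV sidecars
#'
#' `write_counts()` writes `matrix.mtx` (coordinate format), `features.tsv`
#' and `cells.tsv` into a directory; `read_counts()` reads them back.
#' The round trip is exact on integer counts and identifiers.
#'
#' @param dir directory holding (or to hold) `matrix.mtx`, `features.tsv`,
#'   `cells.tsv`. Cell metadata columns beyond the identifier are preserved
#'   in `cells.tsv`.
#' @param m a [cell_gene_matrix()].
#' @return `read_counts()` returns a [cell_gene_matrix()]; `write_counts()`
#'   returns `dir` invisibly.
#' @export
read_counts <- function(dir) {
  mat_path <- file.path(dir, "matrix.mtx")
  feat_path <- file.path(dir, "features.tsv")
  cell_path <- file.path(dir, "cells.tsv")
  for (p in c(mat_path, feat_path, cell_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  counts <- methods::as(Matrix::readMM(mat_path), "CsparseMatrix")
  features <- read.delim(feat_path, header = TRUE, stringsAsFactors = FALSE)
  cells <- read.delim(cell_path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(features) != ncol(counts) || nrow(cells) != nrow(counts)) {
    stop("dimension mismatch between matrix header and sidecar files")
  }
  dimnames(counts) <- list(as.character(cells$cell_id),
                           as.character(features$feature))
  cell_gene_matrix(counts, cells)
}

#' @rdname read_counts
#' @export
write_counts <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  write.table(data.frame(feature = colnames(m$counts)),
              file.path(dir, "features.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(m$cell_meta, file.path(dir, "cells.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
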