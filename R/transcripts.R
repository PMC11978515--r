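#' Transcript tables
#'
#' A transcript table holds one row per decoded read: its 3D position in
#' micrometers, gene identity, phred-scaled quality value (`qv`), an optional
#' cell assignment and an optional nucleus-overlap flag. Unassigned reads
#' carry `NA` in `cell_id`.
#'
#' @param x a data.frame with columns `x`, `y`, `z`, `gene`, `qv` and
#'   optionally `cell_id`, `overlaps_nucleus`.
#' @return a `transcript_table` (a data.frame subclass).
#' @examples
#' tt <- transcript_table(data.frame(
#'   x = c(1, 2), y = c(3, 4), z = 0, gene = c("A", "B"), qv = 30
#' ))
#' nrow(tt)
#' @export
transcript_table <- function(x) {
  stopifnot(is.data.frame(x))
  required <- c("x", "y", "z", "gene", "qv")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("transcript table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("x", "y", "z", "qv")) {
    x[[col]] <- as.numeric(x[[col]])
    bad <- which(!is.finite(x[[col]]))
    if (col == "qv") bad <- union(bad, which(x[[col]] < 0))
    if (length(bad) > 0) {
      stop("non-finite or invalid '", col, "' at row(s) ",
           paste(head(bad, 5), collapse = ", "))
    }
  }
  x$gene <- as.character(x$gene)
  if (is.null(x$cell_id)) {
    x$cell_id <- NA_character_
  } else {
    x$cell_id <- as.character(x$cell_id)
  }
  if (!is.null(x$overlaps_nucleus)) {
    x$overlaps_nucleus <- as.logical(x$overlaps_nucleus)
  }
  rownames(x) <- NULL
  class(x) <- c("transcript_table", "data.frame")
  x
}

#' Read a decoded-transcript table from CSV
#'
#' Reads a per-read transcript export (Xenium `transcripts.csv` dialect by
#' default) into a [transcript_table()]. Coordinates are interpreted as
#' micrometers. Values of the unassigned token (Xenium writes `"UNASSIGNED"`
#' or `-1`) are mapped to `NA`.
#'
#' @param path path to a CSV file.
#' @param dialect named list mapping internal column names (`x`, `y`, `z`,
#'   `gene`, `qv`, `cell_id`, `overlaps_nucleus`) to file column names.
#'   Defaults to the Xenium export names.
#' @param unassigned character vector of tokens in the cell-id column that
#'   denote an unassigned read.
#' @return a [transcript_table()].
#' @export
read_transcripts <- function(path,
                             dialect = xenium_dialect(),
                             unassigned = c("UNASSIGNED", "-1", "")) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading parquet transcript tables requires the 'arrow' package")
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  required <- c("x", "y", "z", "gene", "qv")
  for (key in required) {
    if (!dialect[[key]] %in% names(raw)) {
      stop("required column '", dialect[[key]], "' not found in ", path)
    }
  }
  out <- data.frame(
    x = raw[[dialect$x]],
    y = raw[[dialect$y]],
    z = raw[[dialect$z]],
    gene = raw[[dialect$gene]],
    qv = raw[[dialect$qv]],
    stringsAsFactors = FALSE
  )
  for (col in c("x", "y", "z", "qv")) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !is.na(out[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", col, "' at data row ", bad[1])
    }
    out[[col]] <- vals
  }
  if (dialect$cell_id %in% names(raw)) {
    cid <- as.character(raw[[dialect$cell_id]])
    cid[cid %in% unassigned] <- NA_character_
    out$cell_id <- cid
  }
  if (dialect$overlaps_nucleus %in% names(raw)) {
    out$overlaps_nucleus <- as.logical(as.integer(raw[[dialect$overlaps_nucleus]]))
  }
  transcript_table(out)
}

#' Xenium transcript CSV column dialect
#'
#' @return named list of file column names used by [read_transcripts()].
#' @export
xenium_dialect <- function() {
  list(
    x = "x_location", y = "y_location", z = "z_location",
    gene = "feature_name", qv = "qv", cell_id = "cell_id",
    overlaps_nucleus = "overlaps_nucleus"
  )
}

#' Write a transcript table as CSV in the Xenium dialect
#'
#' @param t a [transcript_table()].
#' @param path output path.
#' @param dialect column-name mapping, see [read_transcripts()].
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(t, path, dialect = xenium_dialect()) {
  out <- data.frame(
    a = t$x, b = t$y, c = t$z, d = t$gene, e = t$qv,
    f = ifelse(is.na(t$cell_id), "UNASSIGNED", t$cell_id),
    stringsAsFactors = FALSE
  )
  nm <- c(dialect$x, dialect$y, dialect$z, dialect$gene, dialect$qv,
          dialect$cell_id)
  if (!is.null(t$overlaps_nucleus)) {
    out$g <- as.integer(t$overlaps_nucleus)
    nm <- c(nm, dialect$overlaps_nucleus)
  }
  names(out) <- nm
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter reads by decoding quality
#'
#' Keeps reads whose phred-scaled quality value exceeds `qv_min` (strict
#' inequality: the conventional Xenium filter `qv > 20` keeps a read with
#' `qv = 20.01` but drops `qv = 20`).
#'
#' @param t a [transcript_table()].
#' @param qv_min quality threshold; reads with `qv > qv_min` are kept.
#' @return the filtered [transcript_table()], row order preserved.
#' @examples
#' tt <- transcript_table(data.frame(
#'   x = 0, y = 0, z = 0, gene = "A", qv = c(10, 20, 20.01, 35)
#' ))
#' nrow(filter_transcripts(tt, 20))  # 2
#' @export
filter_transcripts <- function(t, qv_min = 20) {
  stopifnot(qv_min >= 0)
  out <- t[t$qv > qv_min, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(t)
  out
}

#' Dataset-level QC summary
#'
#' Computes the headline quality descriptors of a decoded dataset: the
#' fraction of reads assigned to cells, the fraction exceeding the quality
#' threshold, and per-cell read/gene statistics over the cells retained in
#' `m`. Per-cell statistics are reported both on all reads of `t` and on the
#' qv-filtered subset, since conventions differ between processing pipelines.
#'
#' @param t the [transcript_table()] the matrix was built from.
#' @param m a [cell_gene_matrix()] derived from `t`.
#' @param qv_min quality threshold used for the high-quality read fraction.
#' @return a list of class `qc_summary` with fields `n_cells`, `n_reads`,
#'   `frac_reads_assigned`, `frac_reads_high_quality`, `mean_reads_per_cell`,
#'   `median_genes_per_cell`, and `filtered` (the same per-cell statistics
#'   computed on reads with `qv > qv_min`).
#' @export
dataset_summary <- function(t, m, qv_min = 20) {
  if (nrow(t) == 0) stop("cannot summarise a table with zero reads")
  n_reads <- nrow(t)
  assigned <- !is.na(t$cell_id)
  per_cell <- function(tab) {
    keep <- !is.na(tab$cell_id) & tab$cell_id %in% rownames(m$counts)
    tab <- tab[keep, , drop = FALSE]
    reads <- table(factor(tab$cell_id, levels = rownames(m$counts)))
    genes <- vapply(
      split(tab$gene, factor(tab$cell_id, levels = rownames(m$counts))),
      function(g) length(unique(g)), numeric(1)
    )
    list(mean_reads = mean(as.numeric(reads)),
         median_genes = median(genes))
  }
  all_stats <- per_cell(t)
  hi <- filter_transcripts(t, qv_min)
  hi_stats <- if (nrow(hi) > 0) per_cell(hi) else
    list(mean_reads = NA_real_, median_genes = NA_real_)
  structure(list(
    n_cells = nrow(m$counts),
    n_reads = n_reads,
    frac_reads_assigned = sum(assigned) / n_reads,
    frac_reads_high_quality = sum(t$qv > qv_min) / n_reads,
    mean_reads_per_cell = all_stats$mean_reads,
    median_genes_per_cell = all_stats$median_genes,
    filtered = list(
      qv_min = qv_min,
      mean_reads_per_cell = hi_stats$mean_reads,
      median_genes_per_cell = hi_stats$median_genes
    )
  ), class = "qc_summary")
}

#' Write a QC summary as JSON or CSV
#'
#' @param qc a [dataset_summary()] result.
#' @param path output path; format inferred from the extension (`.json` or
#'   `.csv`) unless given.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(qc, path,
                             format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  flat <- c(qc[setdiff(names(qc), "filtered")],
            setNames(qc$filtered,
                     paste0("filtered_", names(qc$filtered))))
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(data.frame(metric = names(flat),
                         value = unlist(flat, use.names = FALSE)),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("QC summary\n")
  cat(sprintf("  cells:                %d\n", x$n_cells))
  cat(sprintf("  reads:                %d\n", x$n_reads))
  cat(sprintf("  reads assigned:       %.1f%%\n", 100 * x$frac_reads_assigned))
  cat(sprintf("  reads with qv > %g:   %.1f%%\n",
              x$filtered$qv_min, 100 * x$frac_reads_high_quality))
  cat(sprintf("  mean reads/cell:      %.1f (qv-filtered %.1f)\n",
              x$mean_reads_per_cell, x$filtered$mean_reads_per_cell))
  cat(sprintf("  median genes/cell:    %.1f (qv-filtered %.1f)\n",
              x$median_genes_per_cell, x$filtered$median_genes_per_cell))
  invisible(x)
}
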