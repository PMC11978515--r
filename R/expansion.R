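# normalise a gene-count vector to a composition; zero totals flagged empty
compose <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(NULL)
  counts / tot
}

#' Nuclear expression signatures per cell type
#'
#' Pools nucleus-overlapping reads over all cells of each type and
#' normalises the gene composition to sum to 1.
#'
#' @param t a [transcript_table()] with `overlaps_nucleus` set and cell
#'   assignments present.
#' @param labels data.frame `cell_id`, `cell_type` (or a named vector).
#' @param genes gene universe defining the composition axis; defaults to
#'   the sorted unique genes of `t`.
#' @return matrix of compositions, types x genes; types with zero nuclear
#'   reads are dropped with a warning.
#' @export
nuclear_signatures <- function(t, labels, genes = NULL) {
  if (is.null(t$overlaps_nucleus)) stop("transcript table lacks overlaps_nucleus")
  genes <- genes %||% sort(unique(t$gene))
  lab <- labels_to_vector(labels)
  nuc <- t[!is.na(t$cell_id) & t$overlaps_nucleus %in% TRUE, , drop = FALSE]
  nuc$cell_type <- unname(lab[nuc$cell_id])
  signature_matrix(nuc$cell_type, nuc$gene, genes, what = "cell type")
}

#' Domain background signatures
#'
#' Per tissue domain, the normalised gene composition of reads not assigned
#' to any cell; these extracellular reads approximate the ambient
#' expression signature of the domain.
#'
#' @param t a [transcript_table()].
#' @param domains character vector, one domain label per read of `t`.
#' @param genes gene universe; defaults to the sorted unique genes of `t`.
#' @return matrix of compositions, domains x genes; domains with zero
#'   unassigned reads are dropped with a warning.
#' @export
background_signatures <- function(t, domains, genes = NULL) {
  stopifnot(length(domains) == nrow(t))
  genes <- genes %||% sort(unique(t$gene))
  un <- is.na(t$cell_id)
  signature_matrix(domains[un], t$gene[un], genes, what = "domain")
}

signature_matrix <- function(group, gene, genes, what) {
  keep <- !is.na(group)
  group <- group[keep]; gene <- gene[keep]
  groups <- sort(unique(group))
  tab <- table(factor(group, levels = groups), factor(gene, levels = genes))
  m <- matrix(as.numeric(tab), nrow = length(groups),
              dimnames = list(groups, genes))
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("dropping ", what, "(s) with zero reads: ",
            paste(groups[tot == 0], collapse = ", "))
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  m / tot
}

labels_to_vector <- function(labels) {
  if (is.data.frame(labels)) {
    setNames(as.character(labels$cell_type), labels$cell_id)
  } else {
    labels
  }
}

#' Distance-binned expression signatures
#'
#' Assigns every read to its nearest cell centroid (within `max_dist`), bins
#' reads by that distance into half-open intervals `[d, d + w)`, and returns
#' the normalised gene composition per (cell type, domain, bin). Binning
#' every read -- including extracellular ones -- by nearest-centroid
#' distance is what lets the far bins converge to the domain background.
#'
#' @param t a [transcript_table()].
#' @param centroids data.frame `cell_id`, `x`, `y`.
#' @param labels data.frame `cell_id`, `cell_type` or named vector.
#' @param domains character vector, one domain per read.
#' @param bin_width bin width in um.
#' @param max_dist maximum nearest-centroid distance considered (um).
#' @param genes gene universe; defaults to the sorted unique genes of `t`.
#' @return a list of class `binned_signatures`: `bins` (left edges),
#'   `composition` (named list per "type|domain" of bins x genes
#'   compositions), `counts` (reads per bin), `genes`.
#' @export
distance_binned_signatures <- function(t, centroids, labels, domains,
                                       bin_width = 1, max_dist = 30,
                                       genes = NULL) {
  stopifnot(bin_width > 0, length(domains) == nrow(t))
  genes <- genes %||% sort(unique(t$gene))
  lab <- labels_to_vector(labels)
  nn <- nearest_centroid(t$x, t$y, centroids)
  keep <- nn$dist < max_dist
  d <- nn$dist[keep]
  ty <- unname(lab[centroids$cell_id[nn$index[keep]]])
  dom <- domains[keep]
  gene <- t$gene[keep]
  bin <- floor(d / bin_width)  # 0-based bin index, [d, d + w)
  edges <- seq(0, max_dist - bin_width, by = bin_width)
  n_bins <- length(edges)
  key <- paste(ty, dom, sep = "|")
  comp <- list(); cnt <- list()
  for (k in sort(unique(key))) {
    sel <- key == k
    tab <- table(factor(bin[sel], levels = 0:(n_bins - 1)),
                 factor(gene[sel], levels = genes))
    m <- matrix(as.numeric(tab), nrow = n_bins,
                dimnames = list(format(edges, trim = TRUE), genes))
    tot <- rowSums(m)
    comp[[k]] <- m / ifelse(tot > 0, tot, NA_real_)
    cnt[[k]] <- tot
  }
  structure(list(bins = edges, composition = comp, counts = cnt,
                 genes = genes, bin_width = bin_width),
            class = "binned_signatures")
}

nearest_centroid <- function(x, y, centroids) {
  # chunked brute force: fixtures carry tens to hundreds of cells
  n <- length(x)
  idx <- integer(n); dist <- numeric(n)
  step <- max(1L, floor(2e6 / max(1, nrow(centroids))))
  for (s in seq(1, n, by = step)) {
    e <- min(n, s + step - 1)
    dx <- outer(x[s:e], centroids$x, "-")
    dy <- outer(y[s:e], centroids$y, "-")
    d2 <- dx * dx + dy * dy
    j <- max.col(-d2, ties.method = "first")
    idx[s:e] <- j
    dist[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1), j)])
  }
  list(index = idx, dist = dist)
}

#' Optimal nuclear-expansion distance
#'
#' For each (cell type, domain) pair with enough reads, correlates each
#' distance bin's gene composition with both the type's nuclear signature
#' and the domain's background signature (Pearson, over all panel genes,
#' zeros included). The optimal expansion is the left edge of the smallest
#' bin in which the background correlation exceeds the nuclear correlation
#' -- the distance at which reads stop looking like the cell and start
#' looking like ambient tissue.
#'
#' @param binned a [distance_binned_signatures()] result.
#' @param nuclear types x genes matrix from [nuclear_signatures()].
#' @param background domains x genes matrix from [background_signatures()].
#' @param min_reads minimum total reads for a (type, domain) pair to be
#'   evaluated (5000 in full datasets; lower it for small fixtures).
#' @return a list of class `optimal_expansion`: `per_pair` (data.frame
#'   `cell_type`, `domain`, `crossover`, `n_reads`; `crossover` is `NA`
#'   when no bin crosses), `per_type` (named mean crossover over eligible
#'   domains).
#' @export
optimal_expansion <- function(binned, nuclear, background, min_reads = 5000) {
  genes <- binned$genes
  rows <- list()
  for (k in names(binned$composition)) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    ty <- parts[1]; dom <- parts[2]
    n_reads <- sum(binned$counts[[k]])
    if (n_reads < min_reads) next
    if (!ty %in% rownames(nuclear) || !dom %in% rownames(background)) next
    comp <- binned$composition[[k]]
    nuc <- nuclear[ty, genes]
    bg <- background[dom, genes]
    crossover <- NA_real_
    for (b in seq_along(binned$bins)) {
      v <- comp[b, ]
      if (anyNA(v)) next
      r_nuc <- suppressWarnings(cor(v, nuc))
      r_bg <- suppressWarnings(cor(v, bg))
      if (!is.na(r_nuc) && !is.na(r_bg) && r_bg > r_nuc) {
        crossover <- binned$bins[b]
        break
      }
    }
    rows[[k]] <- data.frame(cell_type = ty, domain = dom,
                            crossover = crossover, n_reads = n_reads,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no (cell type, domain) pair reaches min_reads")
  per_pair <- do.call(rbind, rows)
  rownames(per_pair) <- NULL
  ok <- !is.na(per_pair$crossover)
  per_type <- tapply(per_pair$crossover[ok], per_pair$cell_type[ok], mean)
  structure(list(per_pair = per_pair, per_type = per_type),
            class = "optimal_expansion")
}

#' Nuclear edge distance from transcript positions
#'
#' Estimates each cell's nuclear radius as the mean Euclidean distance from
#' the centroid of its nuclear reads to the vertices of their convex hull.
#' Cells with fewer than three non-collinear nuclear reads are skipped.
#'
#' @param t a [transcript_table()] with `overlaps_nucleus` set, or a list of
#'   per-cell coordinate matrices (columns x, y).
#' @return a list: `per_cell` (named vector of radii), `mean` (mean radius
#'   over evaluated cells), `n_skipped`.
#' @export
nuclear_edge_distance <- function(t) {
  pts <- if (inherits(t, "transcript_table") || is.data.frame(t)) {
    if (is.null(t$overlaps_nucleus)) stop("transcript table lacks overlaps_nucleus")
    nuc <- t[!is.na(t$cell_id) & t$overlaps_nucleus %in% TRUE, , drop = FALSE]
    lapply(split(nuc[, c("x", "y")], nuc$cell_id), as.matrix)
  } else {
    t
  }
  radii <- c(); skipped <- 0
  for (id in names(pts)) {
    p <- pts[[id]]
    if (nrow(p) < 3 || qr(sweep(p, 2, colMeans(p)))$rank < 2) {
      skipped <- skipped + 1
      next
    }
    hull <- grDevices::chull(p[, 1], p[, 2])
    ctr <- colMeans(p)
    radii[id] <- mean(sqrt((p[hull, 1] - ctr[1])^2 + (p[hull, 2] - ctr[2])^2))
  }
  if (skipped > 0) {
    warning(skipped, " cell(s) skipped (fewer than 3 non-collinear nuclear reads)")
  }
  list(per_cell = radii,
       mean = if (length(radii) > 0) mean(radii) else NA_real_,
       n_skipped = skipped)
}
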