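#' Read or write a label image as TIFF
#'
#' Label images are stored as single-channel TIFFs whose pixel values are
#' integer labels (scaled into [0, 1] on disk, as the TIFF writer
#' requires, with the maximum label recorded in the sample format).
#'
#' @param path TIFF file path.
#' @param labels integer label matrix.
#' @param max_label scaling constant used on disk; the same value must be
#'   used for reading and writing.
#' @return `read_label_image()` returns an integer matrix;
#'   `write_label_image()` returns `path` invisibly.
#' @export
read_label_image <- function(path, max_label = 65535L) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("label-image TIFF support requires the 'tiff' package")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * max_label)), nrow(img), ncol(img))
}

#' @rdname read_label_image
#' @export
write_label_image <- function(labels, path, max_label = 65535L) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("label-image TIFF support requires the 'tiff' package")
  }
  if (max(labels) > max_label) stop("labels exceed max_label")
  tiff::writeTIFF(labels / max_label, path, bits.per.sample = 16L)
  invisible(path)
}

#' Expand a label image into the background
#'
#' Grows every label outward into background (label 0) up to `distance`,
#' assigning each contested background pixel to its nearest label (exact
#' Euclidean feature transform), so expanded masks never overlap and the
#' expansion is Voronoi-constrained. Existing labels are never overwritten.
#'
#' @param labels integer matrix, 0 = background.
#' @param distance expansion distance in um (0 = identity).
#' @param pixel_size um per pixel (Xenium morphology images use 0.2125).
#' @return the expanded label matrix.
#' @export
expand_labels <- function(labels, distance, pixel_size = 0.2125) {
  if (!is.matrix(labels) || any(labels != round(labels))) {
    stop("labels must be an integer matrix")
  }
  if (distance == 0) return(labels)
  storage.mode(labels) <- "integer"
  nst <- nearest_site_transform(labels)
  r_px <- distance / pixel_size
  out <- labels
  grow <- labels == 0 & nst$dist2 <= r_px^2
  out[grow] <- nst$label[grow]
  out
}

# map um coordinates to 1-based pixel indices; pixel (i, j) covers
# [(j-1)*s, j*s) x [(i-1)*s, i*s) with x along columns and y along rows
um_to_px <- function(v, pixel_size) floor(v / pixel_size) + 1L

#' Assign reads to segmented cells
#'
#' `mode = "inside"` assigns each read the label under its pixel;
#' `mode = "nearest"` additionally assigns background reads to the closest
#' labeled pixel within `max_dist` (distances measured between pixel
#' centers). Out-of-bounds reads stay unassigned.
#'
#' @param t a [transcript_table()].
#' @param labels integer label matrix (rows = y, cols = x).
#' @param mode `"inside"` or `"nearest"`.
#' @param max_dist maximum centre-to-centre distance (um) for nearest-mode
#'   assignment.
#' @param pixel_size um per pixel.
#' @return `t` with `cell_id` replaced by the label (as character; `NA`
#'   when unassigned).
#' @export
assign_reads <- function(t, labels, mode = c("inside", "nearest"),
                         max_dist = 15, pixel_size = 0.2125) {
  mode <- match.arg(mode)
  storage.mode(labels) <- "integer"
  H <- nrow(labels); W <- ncol(labels)
  i <- um_to_px(t$y, pixel_size)
  j <- um_to_px(t$x, pixel_size)
  inb <- i >= 1 & i <= H & j >= 1 & j <= W
  lab <- rep(0L, nrow(t))
  lab[inb] <- labels[cbind(i[inb], j[inb])]
  if (mode == "nearest") {
    nst <- nearest_site_transform(labels)
    bg <- inb & lab == 0
    d_um <- sqrt(nst$dist2[cbind(i[bg], j[bg])]) * pixel_size
    near <- nst$label[cbind(i[bg], j[bg])]
    near[!(d_um <= max_dist)] <- 0L
    lab[bg] <- near
  }
  t$cell_id <- ifelse(lab > 0, as.character(lab), NA_character_)
  t
}

#' Majority-vote cell typing from a prior annotation
#'
#' When a new segmentation redefines cells, each new cell inherits the most
#' frequent prior type among its reads. Ties break lexicographically (the
#' alphabetically first type wins), which keeps re-runs deterministic.
#'
#' @param new_assignment character vector: per-read cell id (`NA` =
#'   unassigned).
#' @param prior_types character vector: per-read prior type (`NA` =
#'   untyped), same length.
#' @return named character vector, cell id -> type; cells with no typed
#'   reads are absent.
#' @export
majority_vote_types <- function(new_assignment, prior_types) {
  stopifnot(length(new_assignment) == length(prior_types))
  keep <- !is.na(new_assignment) & !is.na(prior_types)
  votes <- split(prior_types[keep], new_assignment[keep])
  vapply(votes, function(v) {
    tab <- table(v)
    names(tab)[which.max(tab)]  # which.max takes the first = lexicographic
  }, character(1))
}

#' Background-intensity false-cell filter
#'
#' Removes segmented cells that are darker than their local background in
#' the nuclear-stain image: the image is tiled into non-overlapping
#' `window`-sized tiles anchored at the origin; within each tile, a cell is
#' deleted when its mean stain intensity is below `factor` times the mean
#' background intensity of the `surround`-sized window centred on the tile
#' (clipped at image edges). Cells spanning tiles are evaluated in the tile
#' holding their centroid. This targets spurious detections in large
#' low-intensity regions.
#'
#' @param labels integer label matrix.
#' @param image numeric matrix of the same shape (grayscale nuclear stain).
#' @param window tile size in pixels.
#' @param surround surround window size in pixels; must be >= `window`.
#' @param factor intensity ratio threshold.
#' @return a list: `labels` (filtered matrix), `removed` (ids removed).
#' @export
background_intensity_filter <- function(labels, image, window = 1000,
                                        surround = 2000, factor = 0.3) {
  stopifnot(identical(dim(labels), dim(image)))
  if (surround < window) stop("surround must be at least the window size")
  storage.mode(labels) <- "integer"
  H <- nrow(labels); W <- ncol(labels)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) return(list(labels = labels, removed = integer(0)))
  px <- which(labels > 0, arr.ind = TRUE)
  lab_px <- labels[px]
  cent_i <- tapply(px[, 1], lab_px, mean)
  cent_j <- tapply(px[, 2], lab_px, mean)
  mean_int <- tapply(image[px], lab_px, mean)
  tile_i <- pmin(floor((cent_i - 1) / window), ceiling(H / window) - 1)
  tile_j <- pmin(floor((cent_j - 1) / window), ceiling(W / window) - 1)
  removed <- integer(0)
  for (tk in unique(paste(tile_i, tile_j))) {
    sel <- paste(tile_i, tile_j) == tk
    ti <- tile_i[sel][1]; tj <- tile_j[sel][1]
    ci <- ti * window + window / 2; cj <- tj * window + window / 2
    half <- surround / 2
    ri <- max(1, floor(ci - half + 1)):min(H, ceiling(ci + half))
    rj <- max(1, floor(cj - half + 1)):min(W, ceiling(cj + half))
    sub_lab <- labels[ri, rj]
    bg <- image[ri, rj][sub_lab == 0]
    if (length(bg) == 0) next
    bg_mean <- mean(bg)
    drop_ids <- as.integer(names(mean_int)[sel][mean_int[sel] < factor * bg_mean])
    removed <- c(removed, drop_ids)
  }
  out <- labels
  out[out %in% removed] <- 0L
  list(labels = out, removed = sort(removed))
}

#' Segmentation-output summary metrics
#'
#' The record used to rank segmentation strategies: the proportion of reads
#' assigned, the number of cells, the median and 5th percentile of reads
#' and genes per cell, and (when a reference is supplied) the raw and
#' permutation-rescaled negative marker purity. Percentiles use linear
#' interpolation (R quantile type 7).
#'
#' @param m a [cell_gene_matrix()] built from `t`; `cell_meta$cell_type`
#'   must be set for the NMP fields.
#' @param t the source [transcript_table()].
#' @param ref optional [reference_profile()] for NMP.
#' @param markers optional precomputed [find_negative_markers()] result.
#' @param n_perm,seed passed to [scaled_nmp()].
#' @return a list of class `seg_summary` with fields `frac_assigned`,
#'   `n_cells`, `median_reads`, `p5_reads`, `median_genes`, `p5_genes`,
#'   `nmp_raw`, `nmp_scaled` (the last two `NA` without a reference).
#' @export
seg_summary <- function(m, t, ref = NULL, markers = NULL, n_perm = 20,
                        seed = 0) {
  reads <- Matrix::rowSums(m$counts)
  genes <- Matrix::rowSums(m$counts > 0)
  nmp_raw <- nmp_scaled <- NA_real_
  if (!is.null(ref)) {
    if (is.null(markers)) markers <- find_negative_markers(ref)
    s <- scaled_nmp(m, ref, markers, n_perm = n_perm, seed = seed)
    nmp_raw <- s$raw; nmp_scaled <- s$scaled
  }
  structure(list(
    frac_assigned = sum(!is.na(t$cell_id)) / nrow(t),
    n_cells = nrow(m$counts),
    median_reads = unname(median(reads)),
    p5_reads = unname(quantile(reads, 0.05, type = 7)),
    median_genes = unname(median(genes)),
    p5_genes = unname(quantile(genes, 0.05, type = 7)),
    nmp_raw = nmp_raw, nmp_scaled = nmp_scaled
  ), class = "seg_summary")
}
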