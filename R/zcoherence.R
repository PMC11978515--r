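#' Gaussian KDE gene-expression vector field
#'
#' Builds a per-gene density field by summing isotropic Gaussian kernels
#' centred at the read positions, evaluated at pixel centres of a regular
#' grid (defaults: 2.5 pixels per um, bandwidth 2.5 um). By default the
#' kernel sum is exact (no truncation); set `truncate` to a finite multiple
#' of the bandwidth to speed up large fields at a controlled approximation
#' error.
#'
#' @param t a [transcript_table()], nonempty.
#' @param resolution pixels per um.
#' @param bandwidth Gaussian kernel sigma in um.
#' @param extent optional `c(xmax, ymax)` in um; defaults to the data
#'   extent.
#' @param genes gene universe ordering the field slices; defaults to the
#'   sorted unique genes of `t`.
#' @param truncate kernel truncation radius in bandwidth units (`Inf` =
#'   exact).
#' @return a list of class `vector_field`: `field` (H x W x G array),
#'   `norm` (H x W L2 norm over genes), `genes`, `resolution`, `bandwidth`.
#'   Pixel (i, j) is centred at ((j - 0.5)/resolution, (i - 0.5)/resolution).
#' @export
kde_field <- function(t, resolution = 2.5, bandwidth = 2.5, extent = NULL,
                      genes = NULL, truncate = Inf) {
  if (nrow(t) == 0) stop("empty transcript table")
  genes <- genes %||% sort(unique(t$gene))
  extent <- extent %||% c(max(t$x), max(t$y))
  W <- max(1L, as.integer(ceiling(extent[1] * resolution)))
  H <- max(1L, as.integer(ceiling(extent[2] * resolution)))
  sigma_px <- bandwidth * resolution
  # pixel-centre coordinates: pixel j spans [(j-1), j) / resolution
  px <- t$x * resolution - 0.5
  py <- t$y * resolution - 0.5
  gi <- match(t$gene, genes)
  if (anyNA(gi)) stop("reads carry genes outside the declared universe")
  trunc_px <- if (is.finite(truncate)) truncate * sigma_px else -1
  field <- kde_accumulate(px, py, gi, length(genes), H, W, sigma_px,
                          trunc_px)
  dimnames(field) <- list(NULL, NULL, genes)
  norm <- sqrt(apply(field^2, c(1, 2), sum))
  structure(list(field = field, norm = norm, genes = genes,
                 resolution = resolution, bandwidth = bandwidth),
            class = "vector_field")
}

#' Split reads into top and bottom tissue halves
#'
#' Bins reads into a square xy grid (default 2 um) and, within each bin,
#' assigns reads above the bin's mean z to the top half and the rest to
#' the bottom half (reads exactly at the mean go to the bottom, so a bin
#' of constant z is all bottom).
#'
#' @param t a [transcript_table()].
#' @param grid xy bin size in um.
#' @return a list with `top` and `bottom` [transcript_table()]s whose union
#'   is the input.
#' @export
split_top_bottom <- function(t, grid = 2) {
  bin <- paste(floor(t$x / grid), floor(t$y / grid))
  mean_z <- ave(t$z, bin, FUN = mean)
  top <- t$z > mean_z
  list(top = t[top, , drop = FALSE], bottom = t[!top, , drop = FALSE])
}

#' Local maxima of a vector-field norm
#'
#' A pixel is a candidate local maximum when its norm is at least that of
#' all 8 neighbours and above `threshold`. Plateaus (adjacent candidates of
#' equal value) keep only their first pixel in column-major order, making
#' the sample set deterministic.
#'
#' @param norm H x W numeric matrix.
#' @param threshold minimum norm for a maximum to be sampled.
#' @return two-column matrix of (row, col) indices.
#' @export
local_maxima <- function(norm, threshold = 0) {
  H <- nrow(norm); W <- ncol(norm)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- norm
  is_max <- matrix(TRUE, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[2:(H + 1) + di, 2:(W + 1) + dj]
    is_max <- is_max & (norm >= nb)
  }
  is_max <- is_max & norm > threshold
  cand <- which(is_max)
  if (length(cand) <= 1) {
    return(cbind(row = row(norm)[cand], col = col(norm)[cand]))
  }
  # drop all but the first pixel of each connected equal-valued plateau
  ci <- row(norm)[cand]; cj <- col(norm)[cand]
  keep <- rep(TRUE, length(cand))
  seen <- new.env()
  for (a in order(cand)) {
    key <- as.character(cand[a])
    if (!is.null(seen[[key]])) { keep[a] <- FALSE; next }
    # flood fill over equal-valued candidate neighbours
    stack <- cand[a]
    seen[[key]] <- TRUE
    val <- norm[cand[a]]
    while (length(stack) > 0) {
      p <- stack[[1]]; stack <- stack[-1]
      pi <- (p - 1) %% H + 1; pj <- (p - 1) %/% H + 1
      for (di in -1:1) for (dj in -1:1) {
        qi <- pi + di; qj <- pj + dj
        if (qi < 1 || qi > H || qj < 1 || qj > W) next
        q <- (qj - 1) * H + qi
        if (q == p || !is.null(seen[[as.character(q)]])) next
        if (q %in% cand && norm[q] == val) {
          seen[[as.character(q)]] <- TRUE
          stack <- c(stack, q)
        }
      }
    }
  }
  cbind(row = ci[keep], col = cj[keep])
}

#' Fit a PCA latent projection on sampled expression vectors
#'
#' Fits principal components on the gene-expression vectors sampled at
#' local maxima of the field norm and keeps the smallest number of
#' components whose cumulative explained variance reaches
#' `variance_target` (read as >= the target).
#'
#' @param samples samples x genes matrix (e.g. field vectors at local
#'   maxima), at least 2 rows.
#' @param variance_target cumulative explained-variance fraction.
#' @return a list of class `latent_projection`: `rotation` (genes x n),
#'   `center`, `n`, `explained` (per-component variance fractions).
#' @export
fit_latent <- function(samples, variance_target = 0.80) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("need at least two sample vectors")
  pca <- prcomp(samples, center = TRUE, scale. = FALSE)
  frac <- pca$sdev^2 / sum(pca$sdev^2)
  n <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  structure(list(rotation = pca$rotation[, seq_len(n), drop = FALSE],
                 center = pca$center, n = n, explained = frac),
            class = "latent_projection")
}

#' Fit the latent projection directly from a full vector field
#'
#' Samples the field's gene vectors at local maxima of its norm and fits
#' the PCA projection on them.
#'
#' @param vf a [kde_field()] result for the full (unsplit) dataset.
#' @param variance_target cumulative explained-variance fraction.
#' @param norm_threshold minimum norm for a local maximum to be sampled.
#' @return a [fit_latent()] projection.
#' @export
fit_latent_from_field <- function(vf, variance_target = 0.80,
                                  norm_threshold = 0) {
  mx <- local_maxima(vf$norm, norm_threshold)
  if (nrow(mx) < 2) stop("fewer than two local maxima above the norm threshold")
  samples <- t(apply(mx, 1, function(rc) vf$field[rc[1], rc[2], ]))
  fit_latent(samples, variance_target)
}

project_field <- function(vf, proj) {
  H <- dim(vf$field)[1]; W <- dim(vf$field)[2]
  flat <- matrix(vf$field, H * W, dim(vf$field)[3])
  lat <- sweep(flat, 2, proj$center) %*% proj$rotation
  array(lat, dim = c(H, W, ncol(lat)))
}

#' Z-axis coherence map
#'
#' Projects the top-half and bottom-half vector fields into the latent
#' space and computes, per pixel, the cosine similarity of the two latent
#' vectors. Pixels where either half's total expression norm falls below
#' `min_norm` (strictly) are low-confidence and marked invalid, as are
#' pixels with a zero projected vector. Low similarity flags locations
#' whose upper and lower tissue halves carry different expression
#' signatures, i.e. cells overlapping in z.
#'
#' @param top,bottom [kde_field()] results of identical shape and gene
#'   order.
#' @param proj a [fit_latent()] projection (fit on the full field).
#' @param min_norm validity threshold on each half's expression norm.
#' @return a list of class `coherence_map`: `similarity` (H x W, `NA`
#'   where invalid), `valid` (H x W logical).
#' @export
coherence_map <- function(top, bottom, proj, min_norm = 5) {
  if (!identical(dim(top$field), dim(bottom$field))) stop("field shape mismatch")
  if (!identical(top$genes, bottom$genes)) stop("gene order mismatch")
  lt <- project_field(top, proj)
  lb <- project_field(bottom, proj)
  dot <- apply(lt * lb, c(1, 2), sum)
  nt <- sqrt(apply(lt^2, c(1, 2), sum))
  nb <- sqrt(apply(lb^2, c(1, 2), sum))
  valid <- top$norm >= min_norm & bottom$norm >= min_norm & nt > 0 & nb > 0
  sim <- matrix(NA_real_, nrow(valid), ncol(valid))
  sim[valid] <- dot[valid] / (nt[valid] * nb[valid])
  structure(list(similarity = sim, valid = valid), class = "coherence_map")
}

#' Flag nuclei with incoherent z-signals
#'
#' Averages the coherence similarity over each nucleus's valid pixels and
#' flags nuclei whose mean falls strictly below `threshold` (default 0.2),
#' indicative of two distinct cells overlapping in z. Nuclei with no valid
#' pixels are left unscored.
#'
#' @param map a [coherence_map()].
#' @param nuclei integer label matrix of nucleus masks, same pixel grid as
#'   the map.
#' @param threshold similarity below which a nucleus is flagged.
#' @return a list: `per_nucleus` (named mean similarity), `flagged` (ids),
#'   `flagged_fraction` (among scored nuclei), `n_unscored`.
#' @export
flag_nuclei <- function(map, nuclei, threshold = 0.2) {
  stopifnot(identical(dim(map$similarity), dim(nuclei)))
  ids <- setdiff(sort(unique(as.vector(nuclei))), 0)
  means <- vapply(ids, function(id) {
    v <- map$similarity[nuclei == id]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  names(means) <- ids
  scored <- !is.na(means)
  flagged <- names(means)[scored & means < threshold]
  list(per_nucleus = means,
       flagged = flagged,
       flagged_fraction = if (any(scored)) length(flagged) / sum(scored)
                          else NA_real_,
       n_unscored = sum(!scored))
}

#' @importFrom stats ave
NULL
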