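#' Filter reference cell types by population size
#'
#' Keeps only cell types represented by at least `min_cells` cells (the
#' conventional cut drops types with ten or fewer cells).
#'
#' @param ref a [reference_profile()].
#' @param min_cells minimum cells per retained type.
#' @return the filtered [reference_profile()].
#' @export
filter_reference <- function(ref, min_cells = 11) {
  tab <- table(ref$cell_type)
  keep_types <- names(tab)[tab >= min_cells]
  if (length(keep_types) == 0) stop("no cell type reaches min_cells")
  keep <- ref$cell_type %in% keep_types
  reference_profile(ref$counts[keep, , drop = FALSE], ref$cell_type[keep])
}

# vectorized one-vs-rest Wilcoxon rank-sum with tie correction; returns
# one-sided (greater-in-group) z-scores per gene
wilcox_z <- function(ranks, tie_term, in_group) {
  n <- nrow(ranks); n1 <- sum(in_group); n2 <- n - n1
  r1 <- colSums(ranks[in_group, , drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (u - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
  z
}

#' Select a targeted panel of top differentially expressed genes
#'
#' Ranks genes per cell type by a one-vs-rest Wilcoxon rank-sum test
#' (greater-in-type alternative; normal approximation with tie
#' correction), breaking ties by higher log fold change and then by gene
#' name, and returns the union of each type's top `n_top` genes -- the
#' standard recipe for composing a targeted in-situ panel.
#'
#' @param ref a [reference_profile()].
#' @param n_top genes kept per cell type.
#' @return a [make_panel()] over the selected genes (reference column
#'   order), with the per-type rankings in attribute `"per_type"`.
#' @export
select_panel <- function(ref, n_top = 50) {
  x <- as.matrix(ref$counts)
  genes <- colnames(x)
  if (n_top > length(genes)) {
    warning("fewer genes than requested; keeping all")
    n_top <- length(genes)
  }
  ranks <- apply(x, 2, rank)
  tie_term <- apply(x, 2, function(col) {
    tj <- table(col)
    sum(tj^3 - tj)
  })
  logx <- log1p(x)
  types <- sort(unique(ref$cell_type))
  per_type <- lapply(types, function(ty) {
    grp <- ref$cell_type == ty
    z <- wilcox_z(ranks, tie_term, grp)
    lfc <- colMeans(logx[grp, , drop = FALSE]) -
      colMeans(logx[!grp, , drop = FALSE])
    ord <- order(-z, -lfc, genes)
    genes[ord[seq_len(n_top)]]
  })
  names(per_type) <- types
  selected <- genes[genes %in% unique(unlist(per_type))]
  p <- make_panel(selected)
  attr(p, "per_type") <- per_type
  p
}

#' Adjust per-gene detection efficiency
#'
#' Resamples every count `c` of gene `g` as `Poisson(e_g * c)`. Poisson
#' resampling covers both thinning (`e_g < 1`) and amplification
#' (`e_g > 1`) with one rule, matching the observation that in-situ
#' efficiency can exceed the scRNA-seq reference for some genes.
#'
#' @param m a [cell_gene_matrix()], [reference_profile()] or counts matrix.
#' @param e named per-gene efficiency vector (> 0); genes absent from `e`
#'   keep efficiency 1.
#' @param seed integer seed.
#' @return the same container type with resampled counts.
#' @export
apply_efficiency <- function(m, e, seed = 0) {
  counts <- extract_counts(m)
  eg <- rep(1, ncol(counts))
  names(eg) <- colnames(counts)
  if (is.null(names(e)) && length(e) == ncol(counts)) {
    eg[] <- e
  } else {
    eg[names(e)] <- e
  }
  if (any(eg <= 0)) stop("efficiencies must be positive")
  cm <- methods::as(counts, "TsparseMatrix")
  newx <- with_seed(seed, rpois(length(cm@x), eg[cm@j + 1L] * cm@x))
  out <- Matrix::sparseMatrix(i = cm@i + 1L, j = cm@j + 1L, x = newx,
                              dims = dim(counts), dimnames = dimnames(counts))
  out <- Matrix::drop0(out)
  rebuild_counts(m, out)
}

extract_counts <- function(m) {
  if (inherits(m, "cell_gene_matrix")) m$counts
  else if (inherits(m, "reference_profile")) m$counts
  else methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
}

rebuild_counts <- function(m, counts) {
  if (inherits(m, "cell_gene_matrix")) cell_gene_matrix(counts, m$cell_meta)
  else if (inherits(m, "reference_profile")) {
    reference_profile(counts, m$cell_type)
  } else counts
}

#' Add non-specific background reads
#'
#' Adds `Poisson(rho / (1 - rho) * total)` spurious reads, each landing in
#' a cell chosen proportionally to its library size and on a gene chosen
#' uniformly over the panel, so the expected share of noise among the
#' final reads is `rho`. Control probes, which receive only non-specific
#' signal, can be given their own rate via `control_rho` and
#' `control_features`.
#'
#' @param m a [cell_gene_matrix()], [reference_profile()] or counts matrix.
#' @param rho target noise fraction of final reads, in `[0, 1)`.
#' @param seed integer seed.
#' @param control_features optional feature names receiving noise at
#'   `control_rho` instead (uniform over these features).
#' @param control_rho noise fraction for the control features.
#' @return the same container type with noise added.
#' @export
add_nonspecific_noise <- function(m, rho, seed = 0,
                                  control_features = NULL,
                                  control_rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  counts <- as.matrix(extract_counts(m))
  with_seed(seed, {
    lib <- rowSums(counts)
    total <- sum(lib)
    main_genes <- setdiff(colnames(counts), control_features)
    sprinkle <- function(genes, frac) {
      if (frac <= 0 || length(genes) == 0) return()
      n_noise <- rpois(1, frac / (1 - frac) * total)
      if (n_noise == 0) return()
      ci <- sample.int(nrow(counts), n_noise, replace = TRUE,
                       prob = if (total > 0) lib else NULL)
      gidx <- match(genes, colnames(counts))
      gi <- gidx[sample.int(length(gidx), n_noise, replace = TRUE)]
      tab <- table(ci, gi)
      idx <- cbind(as.integer(rownames(tab)[row(tab)]),
                   as.integer(colnames(tab)[col(tab)]))
      counts[idx] <<- counts[idx] + as.vector(tab)
    }
    sprinkle(main_genes, rho)
    sprinkle(intersect(control_features, colnames(counts)), control_rho)
  })
  storage.mode(counts) <- "integer"
  rebuild_counts(m, counts)
}

#' Simulate mis-segmentation contamination
#'
#' Picks a fraction `f` of cells as contaminated; each is paired with one
#' uniformly chosen other cell and, per gene, `Binomial(partner count, mix)`
#' reads move from the partner into the contaminated cell. The grand total
#' of reads is conserved; only their cell assignment is corrupted, as when
#' a segmentation boundary cuts through the wrong cell.
#'
#' @param m a [cell_gene_matrix()], [reference_profile()] or counts matrix
#'   with at least two cells.
#' @param f fraction of cells contaminated.
#' @param mix per-read probability of moving from the partner.
#' @param seed integer seed.
#' @return a list: `m` (same container type), `contaminated` (data.frame
#'   `cell`, `partner`).
#' @export
simulate_missegmentation <- function(m, f, mix, seed = 0) {
  stopifnot(f >= 0, f <= 1, mix >= 0, mix <= 1)
  counts <- as.matrix(extract_counts(m))
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  if (n < 2) stop("need at least two cells")
  contaminated <- data.frame(cell = character(0), partner = character(0))
  if (f > 0 && mix > 0) {
    with_seed(seed, {
      targets <- sample.int(n, round(f * n))
      for (cell in targets) {
        partner <- sample(setdiff(seq_len(n), cell), 1)
        moved <- rbinom(ncol(counts), counts[partner, ], mix)
        counts[partner, ] <- counts[partner, ] - moved
        counts[cell, ] <- counts[cell, ] + moved
        contaminated <- rbind(contaminated, data.frame(
          cell = rownames(counts)[cell],
          partner = rownames(counts)[partner]))
      }
    })
  }
  list(m = rebuild_counts(m, counts), contaminated = contaminated)
}

#' Simulate an annotated negative-binomial single-cell reference
#'
#' Generates a cells x genes count matrix with type-specific means: every
#' type owns a block of near-exclusive marker genes expressed
#' `marker_fold` times above baseline in their own type and at the tiny
#' leak mean `marker_leak` in all other types (so markers of one type are
#' negative markers for the others, as in real targeted panels).
#' Non-marker genes share a baseline mean drawn log-uniformly per gene.
#' Counts are negative binomial with variance `mu + dispersion * mu^2`
#' (`dispersion = 0` gives Poisson).
#'
#' @param n_types number of cell types.
#' @param n_genes total genes (markers included).
#' @param cells_per_type cells per type.
#' @param n_markers exclusive marker genes per type.
#' @param marker_fold fold change of a marker in its own type.
#' @param marker_leak mean expression of a marker in the other types.
#' @param baseline_range range of the log-uniform baseline mean.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed integer seed.
#' @return a [reference_profile()]; attribute `"markers"` holds the named
#'   list of designated marker genes per type, attribute `"mu"` the mean
#'   matrix.
#' @export
simulate_reference <- function(n_types = 5, n_genes = 200,
                               cells_per_type = 500, n_markers = 20,
                               marker_fold = 20, marker_leak = 0.002,
                               baseline_range = c(2, 20),
                               dispersion = 0.3, seed = 0) {
  if (n_types * n_markers > n_genes) stop("more markers than genes")
  with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    types <- sprintf("type%d", seq_len(n_types))
    base <- exp(runif(n_genes, log(baseline_range[1]), log(baseline_range[2])))
    mu <- matrix(base, n_types, n_genes, byrow = TRUE,
                 dimnames = list(types, genes))
    markers <- list()
    for (ty in if (n_markers > 0) seq_len(n_types) else integer(0)) {
      idx <- ((ty - 1) * n_markers + 1):(ty * n_markers)
      own <- mu[ty, idx] * marker_fold
      mu[, idx] <- marker_leak
      mu[ty, idx] <- own
      markers[[types[ty]]] <- genes[idx]
    }
    cell_type <- rep(types, each = cells_per_type)
    n_cells <- length(cell_type)
    counts <- matrix(0L, n_cells, n_genes,
                     dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                     genes))
    for (ty in seq_len(n_types)) {
      rows <- which(cell_type == types[ty])
      mu_row <- mu[ty, ]
      draws <- if (dispersion == 0) {
        rpois(length(rows) * n_genes, rep(mu_row, each = length(rows)))
      } else {
        rnbinom(length(rows) * n_genes, mu = rep(mu_row, each = length(rows)),
                size = 1 / dispersion)
      }
      counts[rows, ] <- matrix(draws, length(rows), n_genes)
    }
    ref <- reference_profile(counts, cell_type)
    attr(ref, "markers") <- markers
    attr(ref, "mu") <- mu
    ref
  })
}

#' Spatial fixture configuration
#'
#' Parameters of the spatial point-cloud generator: disk-shaped cells with
#' concentric nuclei packed on a jittered grid, type-specific nuclear and
#' cytoplasmic gene compositions, domain-specific background compositions
#' for extracellular reads, a two-component qv mixture (a high-quality
#' mode near 35 and a low-quality mode near 12, roughly the shape of real
#' decoded-read quality profiles), and optionally two offset z-layers with
#' distinct signatures.
#'
#' @param n_cells number of cells (layer 1).
#' @param n_types cell types in layer 1.
#' @param cell_radius,nucleus_radius disk radii R > r, um.
#' @param gap minimum clearance between cell disks, um.
#' @param n_domains vertical domain strips.
#' @param genes_per_type exclusive genes per cell-type composition.
#' @param genes_per_domain exclusive genes per background composition.
#' @param nuclear_reads,cyto_reads expected reads per cell compartment.
#' @param n_background expected extracellular reads over the whole field.
#' @param z_range z extent, um.
#' @param two_layer add a second z-layer of cells overlapping layer 1 in a
#'   central strip.
#' @param overlap_fraction width fraction of the two-layer overlap strip.
#' @param qv_high_frac,qv_high,qv_low mixture weight and (mean, sd) of the
#'   two qv modes.
#' @param pixel_size um per pixel of the emitted label images.
#' @param seed integer seed (mandatory).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 40, n_types = 2, cell_radius = 10,
                       nucleus_radius = 5, gap = 2, n_domains = 1,
                       genes_per_type = 10, genes_per_domain = 10,
                       nuclear_reads = 120, cyto_reads = 200,
                       n_background = 4000, z_range = c(0, 10),
                       two_layer = FALSE, overlap_fraction = 0.4,
                       qv_high_frac = 0.85, qv_high = c(35, 3),
                       qv_low = c(12, 4), pixel_size = 0.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nucleus_radius < cell_radius, n_cells >= 1, n_types >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Rasterize disks into a label image
#'
#' Paints disk `i` (centre `x[i]`, `y[i]`, common `radius`) with label `i`
#' onto a pixel grid; rows index y, columns x, and pixel (i, j) is centred
#' at ((j - 0.5), (i - 0.5)) * `pixel_size` um. Later disks overwrite
#' earlier ones where they overlap.
#'
#' @param x,y disk centres in um.
#' @param radius disk radius in um.
#' @param extent `c(xmax, ymax)` in um.
#' @param pixel_size um per pixel.
#' @return integer label matrix.
#' @export
rasterize_disks <- function(x, y, radius, extent, pixel_size = 0.5) {
  W <- as.integer(ceiling(extent[1] / pixel_size))
  H <- as.integer(ceiling(extent[2] / pixel_size))
  cx <- (seq_len(W) - 0.5) * pixel_size
  cy <- (seq_len(H) - 0.5) * pixel_size
  img <- matrix(0L, H, W)
  for (i in seq_along(x)) {
    xi <- which(abs(cx - x[i]) <= radius)
    yi <- which(abs(cy - y[i]) <= radius)
    if (length(xi) == 0 || length(yi) == 0) next
    sub <- outer(cy[yi] - y[i], cx[xi] - x[i],
                 function(a, b) a^2 + b^2) <= radius^2
    img[yi, xi][sub] <- i
  }
  img
}

# composition vector over the global gene universe concentrated on a block,
# with mildly decaying weights so bins are informative but not degenerate
block_composition <- function(genes, block) {
  w <- setNames(numeric(length(genes)), genes)
  w[block] <- exp(-0.15 * seq_along(block))
  w / sum(w)
}

#' Generate a spatial transcript fixture with ground truth
#'
#' Places non-overlapping disk cells (radius R) with concentric nuclei
#' (radius r) on a jittered grid, draws nuclear reads from each type's
#' nuclear composition inside r, cytoplasmic reads from the type
#' composition in `[r, R)`, and extracellular background reads from the
#' domain composition outside all cells. Emits the transcript table, cell
#' and nucleus label images, and the full generating truth. With
#' `two_layer`, cells in a central strip get a partner cell at the same
#' xy position in a second z-layer with a distinct (disjoint-gene)
#' signature, emulating two cells stacked in z.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `spatial_fixture`: `transcripts`
#'   ([transcript_table()]), `cells`/`nuclei` (label matrices),
#'   `domains` (per-read domain), `truth` (cells data.frame, panel,
#'   compositions, overlap nuclei, config).
#' @export
generate_spatial_fixture <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    R <- cfg$cell_radius; r <- cfg$nucleus_radius
    spacing <- 2 * R + cfg$gap
    ngrid <- ceiling(sqrt(cfg$n_cells))
    if (ngrid^2 < cfg$n_cells) stop("cells cannot be packed on the grid")
    field <- ngrid * spacing
    slots <- expand.grid(gx = seq_len(ngrid), gy = seq_len(ngrid))
    slots <- slots[sample.int(nrow(slots), cfg$n_cells), ]
    jit <- cfg$gap / 2 - 1e-6
    cx <- (slots$gx - 0.5) * spacing + runif(cfg$n_cells, -jit, jit)
    cy <- (slots$gy - 0.5) * spacing + runif(cfg$n_cells, -jit, jit)

    # gene universe: per-type blocks, per-domain background blocks, and a
    # second set of type blocks for the optional second layer
    types1 <- sprintf("type%d", seq_len(cfg$n_types))
    types2 <- if (cfg$two_layer) sprintf("ztype%d", seq_len(cfg$n_types))
              else character(0)
    domains <- sprintf("domain%d", seq_len(cfg$n_domains))
    gene_blocks <- c(
      lapply(seq_along(types1), function(i)
        sprintf("T%d_g%02d", i, seq_len(cfg$genes_per_type))),
      lapply(seq_along(types2), function(i)
        sprintf("Z%d_g%02d", i, seq_len(cfg$genes_per_type))),
      lapply(seq_along(domains), function(i)
        sprintf("D%d_g%02d", i, seq_len(cfg$genes_per_domain)))
    )
    names(gene_blocks) <- c(types1, types2, domains)
    genes <- unlist(gene_blocks, use.names = FALSE)
    comp <- lapply(gene_blocks, function(b) block_composition(genes, b))

    z0 <- cfg$z_range[1]; zspan <- diff(cfg$z_range)
    cells <- data.frame(
      cell_id = sprintf("cell%03d", seq_len(cfg$n_cells)),
      x = cx, y = cy,
      cell_type = sample(types1, cfg$n_cells, replace = TRUE),
      layer = 1L, stringsAsFactors = FALSE
    )
    overlap_ids <- character(0)
    if (cfg$two_layer) {
      half_w <- cfg$overlap_fraction * field / 2
      in_strip <- abs(cells$x - field / 2) <= half_w
      overlap_ids <- cells$cell_id[in_strip]
      partners <- data.frame(
        cell_id = sprintf("zcell%03d", seq_len(sum(in_strip))),
        x = cells$x[in_strip], y = cells$y[in_strip],
        cell_type = sample(types2, sum(in_strip), replace = TRUE),
        layer = 2L, stringsAsFactors = FALSE
      )
      cells <- rbind(cells, partners)
    }

    draw_cell_reads <- function(cell, n, r_lo, r_hi, composition, nuclear) {
      if (n == 0) return(NULL)
      rad <- sqrt(runif(n, r_lo^2, r_hi^2))
      ang <- runif(n, 0, 2 * pi)
      z <- if (!cfg$two_layer) runif(n, z0, z0 + zspan)
           else if (cell$layer == 1L) runif(n, z0, z0 + 0.4 * zspan)
           else runif(n, z0 + 0.6 * zspan, z0 + zspan)
      data.frame(
        x = cell$x + rad * cos(ang), y = cell$y + rad * sin(ang), z = z,
        gene = sample(genes, n, replace = TRUE, prob = composition),
        cell_id = cell$cell_id, overlaps_nucleus = nuclear,
        stringsAsFactors = FALSE
      )
    }

    reads <- list()
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      cc <- comp[[cell$cell_type]]
      reads[[2 * i - 1]] <- draw_cell_reads(cell, rpois(1, cfg$nuclear_reads),
                                            0, r, cc, TRUE)
      reads[[2 * i]] <- draw_cell_reads(cell, rpois(1, cfg$cyto_reads),
                                        r, R, cc, FALSE)
    }

    # extracellular background: uniform over the field outside all disks
    n_bg <- rpois(1, cfg$n_background)
    bx <- numeric(0); by <- numeric(0)
    while (length(bx) < n_bg) {
      m <- (n_bg - length(bx)) * 2 + 10
      px <- runif(m, 0, field); py <- runif(m, 0, field)
      d2 <- outer(px, cells$x[cells$layer == 1L], "-")^2 +
            outer(py, cells$y[cells$layer == 1L], "-")^2
      free <- apply(d2, 1, min) > R^2
      bx <- c(bx, px[free]); by <- c(by, py[free])
    }
    bx <- bx[seq_len(n_bg)]; by <- by[seq_len(n_bg)]
    dom_of_x <- function(x) {
      sprintf("domain%d", pmin(cfg$n_domains,
                               floor(x / (field / cfg$n_domains)) + 1))
    }
    bg_dom <- dom_of_x(bx)
    bg_gene <- vapply(bg_dom, function(d)
      sample(genes, 1, prob = comp[[d]]), character(1))
    if (n_bg > 0) {
      reads[[length(reads) + 1]] <- data.frame(
        x = bx, y = by, z = runif(n_bg, z0, z0 + zspan),
        gene = unname(bg_gene), cell_id = NA_character_,
        overlaps_nucleus = FALSE, stringsAsFactors = FALSE
      )
    }
    tt <- do.call(rbind, reads[!vapply(reads, is.null, logical(1))])

    n_reads <- nrow(tt)
    hi <- runif(n_reads) < cfg$qv_high_frac
    qv <- ifelse(hi, rnorm(n_reads, cfg$qv_high[1], cfg$qv_high[2]),
                 rnorm(n_reads, cfg$qv_low[1], cfg$qv_low[2]))
    tt$qv <- pmax(qv, 0)
    tt <- transcript_table(tt)

    # label images: layer-1 geometry only (a 2D stain sees one focal plane)
    lay1 <- cells[cells$layer == 1L, ]
    paint <- function(radius) {
      rasterize_disks(lay1$x, lay1$y, radius, extent = c(field, field),
                      pixel_size = cfg$pixel_size)
    }
    structure(list(
      transcripts = tt,
      cells = paint(R),
      nuclei = paint(r),
      domains = dom_of_x(tt$x),
      truth = list(cells = cells, genes = genes, compositions = comp,
                   overlap_nuclei = overlap_ids, field_size = field,
                   label_ids = setNames(seq_len(nrow(lay1)), lay1$cell_id),
                   config = cfg)
    ), class = "spatial_fixture")
  })
}
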