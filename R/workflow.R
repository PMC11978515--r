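#' Preprocessing-workflow configuration
#'
#' Describes one cell-by-gene preprocessing path: normalization -> log ->
#' HVF selection -> scaling -> PCA -> kNN graph -> clustering, with each
#' step optional. Pearson-residual normalization forces the log step off
#' (residuals are already variance-stabilised). The default configuration
#' is the top-performing path for Xenium-like data: library-size
#' normalization to 100 counts, log transform, scaling, all principal
#' components, 16 neighbors, Louvain.
#'
#' @param normalization one of `"library_size"`, `"pearson_residuals"`,
#'   `"none"`.
#' @param target library-size target: a number (10, 100, 1000, ...) or
#'   `"median"` for the median library size.
#' @param log_transform apply `log1p` after normalization.
#' @param hvf_selection keep only highly variable features.
#' @param n_hvf number of highly variable features when `hvf_selection`.
#' @param scaling z-score each gene.
#' @param n_pcs number of principal components, or `NULL` for all computed
#'   components (capped at `max_pcs`).
#' @param max_pcs cap applied when `n_pcs` is `NULL`.
#' @param n_neighbors kNN graph degree.
#' @param clustering `"louvain"` or `"leiden"`.
#' @param resolution clustering resolution.
#' @param seed RNG seed used for clustering.
#' @param theta inverse-overdispersion for Pearson residuals.
#' @return a list of class `workflow_config`.
#' @export
workflow_config <- function(normalization = c("library_size",
                                              "pearson_residuals", "none"),
                            target = 100,
                            log_transform = TRUE,
                            hvf_selection = FALSE,
                            n_hvf = 2000,
                            scaling = TRUE,
                            n_pcs = NULL,
                            max_pcs = 50,
                            n_neighbors = 16,
                            clustering = c("louvain", "leiden"),
                            resolution = 1,
                            seed = 0,
                            theta = 100) {
  normalization <- match.arg(normalization)
  clustering <- match.arg(clustering)
  if (normalization == "pearson_residuals") log_transform <- FALSE
  structure(list(normalization = normalization, target = target,
                 log_transform = log_transform,
                 hvf_selection = hvf_selection, n_hvf = n_hvf,
                 scaling = scaling, n_pcs = n_pcs, max_pcs = max_pcs,
                 n_neighbors = n_neighbors, clustering = clustering,
                 resolution = resolution, seed = seed, theta = theta),
            class = "workflow_config")
}

# analytic Pearson residuals under a NB null with fixed theta; clipped at
# +/- sqrt(n) as is conventional
pearson_residuals <- function(x, theta = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  lib <- rowSums(x)
  pg <- colSums(x) / sum(x)
  mu <- outer(lib, pg)
  r <- (x - mu) / sqrt(mu + mu^2 / theta)
  r[!is.finite(r)] <- 0
  pmin(pmax(r, -sqrt(n)), sqrt(n))
}

#' Run one preprocessing workflow
#'
#' Executes the enabled steps in the fixed order normalization -> log ->
#' HVF -> scale -> PCA -> kNN graph -> clustering and returns the cluster
#' labels. Deterministic given `cfg$seed`.
#'
#' @param m a [cell_gene_matrix()] or counts matrix (cells x genes).
#' @param cfg a [workflow_config()].
#' @return integer cluster labels (one per cell), with the achieved number
#'   of clusters as attribute `"k"` and the embedding as attribute `"pca"`.
#' @export
run_workflow <- function(m, cfg = workflow_config()) {
  counts <- if (inherits(m, "cell_gene_matrix")) m$counts else m
  x <- as.matrix(counts)

  x <- switch(cfg$normalization,
    library_size = {
      lib <- rowSums(x)
      target <- if (identical(cfg$target, "median")) median(lib) else cfg$target
      sweep(x, 1, ifelse(lib > 0, lib, 1), "/") * target
    },
    pearson_residuals = pearson_residuals(x, cfg$theta),
    none = x
  )
  if (cfg$log_transform) x <- log1p(x)
  if (cfg$hvf_selection) {
    v <- apply(x, 2, var)
    keep <- order(v, decreasing = TRUE)[seq_len(min(cfg$n_hvf, ncol(x)))]
    x <- x[, sort(keep), drop = FALSE]
  }
  if (cfg$scaling) {
    s <- apply(x, 2, sd)
    x <- sweep(sweep(x, 2, colMeans(x)), 2, ifelse(s > 0, s, 1), "/")
  }

  n_pcs <- cfg$n_pcs %||% min(cfg$max_pcs, nrow(x) - 1, ncol(x))
  if (n_pcs > min(nrow(x) - 1, ncol(x))) {
    stop("n_pcs exceeds the rank bound min(cells - 1, genes)")
  }
  pca <- prcomp(x, rank. = n_pcs, center = !cfg$scaling)
  emb <- pca$x

  g <- knn_graph(emb, cfg$n_neighbors)
  comm <- with_seed(cfg$seed, switch(cfg$clustering,
    louvain = igraph::cluster_louvain(g, resolution = cfg$resolution),
    leiden = igraph::cluster_leiden(g, objective_function = "modularity",
                                    resolution = cfg$resolution,
                                    n_iterations = 3)
  ))
  labels <- as.integer(igraph::membership(comm))
  attr(labels, "k") <- length(unique(labels))
  attr(labels, "pca") <- emb
  labels
}

# undirected kNN graph on a Euclidean embedding (union of directed kNN)
knn_graph <- function(emb, k) {
  n <- nrow(emb)
  k <- min(k, n - 1)
  d2 <- as.matrix(stats::dist(emb))^2
  diag(d2) <- Inf
  edges <- lapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    cbind(i, nb)
  })
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Tune clustering resolution to a target cluster count
#'
#' Bisects the resolution in `[1e-3, 10]` until the achieved number of
#' clusters is within `tol` of `target_k` (at most `max_iter` evaluations);
#' if no resolution lands inside the tolerance the closest one found is
#' returned, flagged. Cluster count is not assumed strictly monotone in
#' resolution, so the best candidate is tracked across all evaluations.
#'
#' @param cluster_fn function(resolution) -> label vector.
#' @param target_k desired number of clusters.
#' @param tol acceptable deviation (default +/- 2 clusters).
#' @param lower,upper resolution bracket.
#' @param max_iter maximum evaluations.
#' @return a list: `resolution`, `labels`, `k`, `converged`.
#' @export
tune_resolution <- function(cluster_fn, target_k, tol = 2,
                            lower = 1e-3, upper = 10, max_iter = 25) {
  best <- NULL
  lo <- lower; hi <- upper
  for (iter in seq_len(max_iter)) {
    res <- if (iter == 1) lower else if (iter == 2) upper else (lo + hi) / 2
    labels <- cluster_fn(res)
    k <- length(unique(labels))
    if (is.null(best) || abs(k - target_k) < abs(best$k - target_k)) {
      best <- list(resolution = res, labels = labels, k = k)
    }
    if (abs(k - target_k) <= tol) {
      return(c(best, list(converged = TRUE)))
    }
    if (iter >= 2) {
      if (k < target_k) lo <- res else hi <- res
      if (hi - lo < 1e-6) break
    }
  }
  c(best, list(converged = FALSE))
}

#' Run a workflow with resolution tuned to a target cluster count
#'
#' Convenience wrapper combining [run_workflow()] and [tune_resolution()].
#'
#' @inheritParams run_workflow
#' @param target_k desired number of clusters (e.g. the number of reference
#'   cell types).
#' @param tol cluster-count tolerance.
#' @return as [tune_resolution()].
#' @export
run_workflow_tuned <- function(m, cfg = workflow_config(), target_k,
                               tol = 2) {
  tune_resolution(function(res) {
    cfg$resolution <- res
    run_workflow(m, cfg)
  }, target_k = target_k, tol = tol)
}

#' One-step-at-a-time workflow perturbation
#'
#' Re-runs a workflow with a single step modified and reports the
#' partition similarity to the base workflow's clusters, quantifying how
#' much that step matters.
#'
#' @param m a [cell_gene_matrix()] or counts matrix.
#' @param base_cfg the reference [workflow_config()].
#' @param step name of the config field to perturb (e.g. `"scaling"`,
#'   `"log_transform"`, `"normalization"`, `"hvf_selection"`).
#' @param value the perturbed value; logical steps default to their toggle.
#' @param base_labels optional precomputed base labels (recomputed
#'   otherwise).
#' @return a list: `comparison` ([compare_partitions()] result), `labels`,
#'   `step`, `value`.
#' @export
perturb_and_score <- function(m, base_cfg, step, value = NULL,
                              base_labels = NULL) {
  if (!step %in% names(base_cfg)) stop("unknown workflow step: ", step)
  if (is.null(base_labels)) base_labels <- run_workflow(m, base_cfg)
  cfg <- base_cfg
  if (is.null(value)) {
    if (!is.logical(cfg[[step]])) {
      stop("supply `value` for non-logical step '", step, "'")
    }
    value <- !cfg[[step]]
  }
  cfg[[step]] <- value
  if (cfg$normalization == "pearson_residuals") cfg$log_transform <- FALSE
  labels <- run_workflow(m, cfg)
  list(comparison = compare_partitions(base_labels, labels),
       labels = labels, step = step, value = value)
}

#' Per-gene imputation accuracy metrics
#'
#' Scores predicted against measured expression gene by gene with four
#' complementary metrics: Pearson correlation (raw vectors), SSIM (on
#' min-max-scaled vectors, stabilisation constants C1 = 0.01^2,
#' C2 = 0.03^2 at dynamic range 1, sample moments), RMSE (on per-gene
#' z-scored vectors) and Jensen-Shannon divergence (vectors normalised to
#' sum 1, natural log, 0 log 0 := 0). Higher PCC/SSIM and lower RMSE/JS
#' indicate better prediction.
#'
#' @param true_expr,pred_expr cells x genes matrices, same shape and
#'   dimnames.
#' @return data.frame with one row per gene: `gene`, `pcc`, `ssim`,
#'   `rmse`, `js`. Constant measured vectors yield `NA` PCC (flagged by a
#'   warning).
#' @export
imputation_metrics <- function(true_expr, pred_expr) {
  true_expr <- as.matrix(true_expr); pred_expr <- as.matrix(pred_expr)
  if (!identical(dim(true_expr), dim(pred_expr))) stop("shape mismatch")
  genes <- colnames(true_expr) %||% as.character(seq_len(ncol(true_expr)))
  res <- lapply(seq_along(genes), function(g) {
    x <- true_expr[, g]; y <- pred_expr[, g]
    pcc <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    data.frame(gene = genes[g], pcc = pcc, ssim = ssim_vec(x, y),
               rmse = rmse_z(x, y), js = js_divergence(x, y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$pcc)) warning("PCC undefined for constant vector(s)")
  out
}

minmax <- function(x) {
  r <- max(x) - min(x)
  if (r == 0) rep(0, length(x)) else (x - min(x)) / r
}

ssim_vec <- function(x, y, c1 = 0.01^2, c2 = 0.03^2) {
  x <- minmax(x); y <- minmax(y)
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  cxy <- if (length(x) > 1) cov(x, y) else 0
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

rmse_z <- function(x, y) {
  zs <- function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v)
  sqrt(mean((zs(x) - zs(y))^2))
}

js_divergence <- function(x, y) {
  if (any(x < 0) || any(y < 0)) stop("JS divergence needs nonnegative vectors")
  p <- if (sum(x) == 0) rep(1 / length(x), length(x)) else x / sum(x)
  q <- if (sum(y) == 0) rep(1 / length(y), length(y)) else y / sum(y)
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' @importFrom stats cov
NULL
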