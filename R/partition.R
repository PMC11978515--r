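#' Compare two partitions of the same cells
#'
#' Computes four contingency-table similarity statistics between two
#' clusterings: the adjusted Rand index (ARI, permutation-model adjusted),
#' the variation of information (VI, entropies in nats), normalized mutual
#' information (NMI, arithmetic-mean normalisation) and the Fowlkes-Mallows
#' index (FMI). Identical partitions give (1, 0, 1, 1).
#'
#' @param a,b cluster label vectors over the same cells, same order.
#' @return a list of class `partition_comparison` with `ari`, `vi`, `nmi`,
#'   `fmi`.
#' @examples
#' compare_partitions(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
compare_partitions <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same cells")
  n <- length(a)
  tab <- table(a, b)
  ai <- rowSums(tab)
  bj <- colSums(tab)

  # pair counts
  comb2 <- function(x) x * (x - 1) / 2
  sum_nij <- sum(comb2(tab))
  sum_ai <- sum(comb2(ai))
  sum_bj <- sum(comb2(bj))
  total <- comb2(n)
  expected <- sum_ai * sum_bj / total
  max_index <- (sum_ai + sum_bj) / 2
  ari <- if (max_index == expected) {
    if (sum_nij == max_index) 1 else 0
  } else {
    (sum_nij - expected) / (max_index - expected)
  }

  # entropies and mutual information (nats)
  p <- tab / n; pa <- ai / n; pb <- bj / n
  plogp <- function(x) sum(ifelse(x > 0, x * log(x), 0))
  ha <- -plogp(pa); hb <- -plogp(pb)
  mi <- 0
  nz <- which(tab > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    pij <- p[nz[r, 1], nz[r, 2]]
    mi <- mi + pij * log(pij / (pa[nz[r, 1]] * pb[nz[r, 2]]))
  }
  mi <- unname(mi)
  vi <- ha + hb - 2 * mi
  denom <- (ha + hb) / 2
  nmi <- if (denom == 0) 1 else mi / denom
  fmi <- if (sum_ai == 0 || sum_bj == 0) {
    if (sum_ai == sum_bj) 1 else 0
  } else {
    sum_nij / sqrt(sum_ai * sum_bj)
  }
  structure(list(ari = ari, vi = max(0, vi), nmi = nmi, fmi = fmi),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf("ARI %.4f  VI %.4f  NMI %.4f  FMI %.4f\n",
              x$ari, x$vi, x$nmi, x$fmi))
  invisible(x)
}

#' Split genes into cross-validation folds
#'
#' Shuffles the genes with a seeded RNG and deals them into `k` disjoint
#' folds whose sizes differ by at most one, as used for leave-fold-out gene
#' imputation benchmarks.
#'
#' @param genes character vector of gene names.
#' @param k number of folds.
#' @param seed integer seed.
#' @return a list of `k` character vectors covering `genes` exactly once.
#' @export
crossval_gene_split <- function(genes, k = 10, seed = 0) {
  if (k > length(genes)) stop("more folds than genes")
  shuffled <- with_seed(seed, sample(genes))
  split(shuffled, rep(seq_len(k), length.out = length(genes)))
}

#' Control-probe false-positive rate for SVF callers
#'
#' Control probes have no biological target and can never be genuinely
#' spatially variable, so the fraction of control probes a spatially
#' variable feature (SVF) caller selects estimates its false-positive rate.
#'
#' @param svf_calls named logical vector: per-feature SVF call.
#' @param panel a [make_panel()] with at least one control probe.
#' @return fraction of control probes called spatially variable.
#' @export
control_probe_fpr <- function(svf_calls, panel) {
  controls <- panel$features[panel$is_control]
  if (length(controls) == 0) stop("panel has no control probes")
  calls <- svf_calls[controls]
  if (anyNA(calls)) stop("missing SVF call for control probe(s): ",
                         paste(controls[is.na(calls)], collapse = ", "))
  mean(calls)
}
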