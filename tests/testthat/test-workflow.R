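test_that("partition metrics match direct contingency-table evaluation", {
  # identity
  ident <- compare_partitions(c(1, 1, 2, 2), c("x", "x", "y", "y"))
  expect_equal(unclass(ident)[c("ari", "vi", "nmi", "fmi")],
               list(ari = 1, vi = 0, nmi = 1, fmi = 1))
  # singletons vs one block, n = 4: ARI = 0 by the adjustment
  deg <- compare_partitions(1:4, rep(1, 4))
  expect_equal(deg$ari, 0)
  # random partitions against an independent formula implementation
  direct <- function(a, b) {
    n <- length(a); tab <- table(a, b)
    nij <- as.vector(tab); ai <- rowSums(tab); bj <- colSums(tab)
    ch <- function(x) x * (x - 1) / 2
    ari <- (sum(ch(nij)) - sum(ch(ai)) * sum(ch(bj)) / ch(n)) /
      ((sum(ch(ai)) + sum(ch(bj))) / 2 - sum(ch(ai)) * sum(ch(bj)) / ch(n))
    H <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
    pij <- tab / n
    mi <- sum(ifelse(pij > 0,
                     pij * log(pij / outer(ai / n, bj / n)), 0))
    list(ari = ari, vi = H(ai / n) + H(bj / n) - 2 * mi,
         nmi = mi / ((H(ai / n) + H(bj / n)) / 2),
         fmi = sum(ch(nij)) / sqrt(sum(ch(ai)) * sum(ch(bj))))
  }
  set.seed(55)
  for (rep in 1:10) {
    a <- sample(1:4, 30, TRUE); b <- sample(1:3, 30, TRUE)
    got <- compare_partitions(a, b)
    want <- direct(a, b)
    expect_equal(got$ari, want$ari, tolerance = 1e-12)
    expect_equal(got$vi, want$vi, tolerance = 1e-12)
    expect_equal(got$nmi, want$nmi, tolerance = 1e-12)
    expect_equal(got$fmi, want$fmi, tolerance = 1e-12)
    # symmetry
    rev <- compare_partitions(b, a)
    expect_equal(rev$ari, got$ari)
    expect_equal(rev$vi, got$vi)
  }
  expect_error(compare_partitions(1:3, 1:4), "same cells")
})

test_that("partition metrics agree with external implementations", {
  set.seed(7)
  a <- sample(1:5, 40, TRUE); b <- sample(1:4, 40, TRUE)
  got <- compare_partitions(a, b)
  expect_equal(got$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  expect_equal(got$vi, igraph::compare(a, b, method = "vi"),
               tolerance = 1e-12)
})

test_that("gene folds are disjoint, exhaustive and balanced", {
  genes <- paste0("g", 1:20)
  folds <- crossval_gene_split(genes, k = 10, seed = 1)
  expect_length(folds, 10)
  expect_true(all(lengths(folds) == 2))
  expect_setequal(unlist(folds), genes)
  folds21 <- crossval_gene_split(paste0("g", 1:21), k = 10, seed = 1)
  expect_equal(unname(sort(lengths(folds21), decreasing = TRUE)[1]), 3L)
  expect_equal(sum(lengths(folds21) == 2), 9)
  # seeded determinism
  expect_identical(folds, crossval_gene_split(genes, 10, seed = 1))
  expect_error(crossval_gene_split(genes, 21), "folds")
})

test_that("imputation metrics hit identity values and match formulas", {
  set.seed(31)
  x <- matrix(rpois(200, 5), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  self <- imputation_metrics(x, x)
  expect_equal(self$pcc, rep(1, 4))
  expect_equal(self$ssim, rep(1, 4), tolerance = 1e-9)
  expect_equal(self$rmse, rep(0, 4))
  expect_equal(self$js, rep(0, 4))
  # anti-correlation
  anti <- imputation_metrics(x, max(x) - x)
  expect_equal(anti$pcc, rep(-1, 4))
  # independent formula implementation on random pairs
  y <- matrix(rpois(200, 5) + 1, 50, 4)
  got <- imputation_metrics(x, y)
  for (g in 1:4) {
    a <- x[, g]; b <- y[, g]
    expect_equal(got$pcc[g], cor(a, b), tolerance = 1e-12)
    mm <- function(v) (v - min(v)) / (max(v) - min(v))
    am <- mm(a); bm <- mm(b)
    c1 <- 1e-4; c2 <- 9e-4
    want_ssim <- ((2 * mean(am) * mean(bm) + c1) * (2 * cov(am, bm) + c2)) /
      ((mean(am)^2 + mean(bm)^2 + c1) * (var(am) + var(bm) + c2))
    expect_equal(got$ssim[g], want_ssim, tolerance = 1e-12)
    za <- scale(a)[, 1]; zb <- scale(b)[, 1]
    expect_equal(got$rmse[g], sqrt(mean((za - zb)^2)), tolerance = 1e-12)
    p <- a / sum(a); q <- b / sum(b); m <- (p + q) / 2
    kl <- function(u, v) sum(ifelse(u > 0, u * log(u / v), 0))
    expect_equal(got$js[g], 0.5 * kl(p, m) + 0.5 * kl(q, m),
                 tolerance = 1e-12)
  }
  expect_warning(imputation_metrics(matrix(1, 5, 1), matrix(1:5, 5, 1)),
                 "constant")
})

test_that("control-probe FPR counts calls over control probes only", {
  p <- make_panel(c("Actb", "Vim", paste0("NegControlProbe_", 1:20)))
  calls <- setNames(rep(FALSE, 22), p$features)
  expect_equal(control_probe_fpr(calls, p), 0)
  calls["NegControlProbe_7"] <- TRUE
  calls["Actb"] <- TRUE  # real gene calls never count
  expect_equal(control_probe_fpr(calls, p), 0.05)
  set.seed(2)
  calls[] <- runif(22) < 0.5
  expect_equal(control_probe_fpr(calls, p),
               mean(calls[grepl("NegControl", names(calls))]))
  expect_error(control_probe_fpr(calls, make_panel(c("a", "b"))), "control")
})

test_that("resolution tuning lands within tolerance on a monotone oracle", {
  # synthetic monotone cluster-count function k(res) = floor(10 * res)
  fn <- function(res) rep(seq_len(max(1, floor(10 * res))), length.out = 50)
  tuned <- tune_resolution(fn, target_k = 6, tol = 0)
  expect_true(tuned$converged)
  expect_equal(tuned$k, 6)
  # grid-scan oracle: some resolution in [1e-3, 10] achieves k = 6
  ks <- sapply(seq(0.05, 1, by = 0.05), function(r) length(unique(fn(r))))
  expect_true(6 %in% ks)
  # boundary: target 1 reachable at the bottom of the bracket
  tuned1 <- tune_resolution(fn, target_k = 1, tol = 0)
  expect_equal(tuned1$k, 1)
})

test_that("the workflow is deterministic and respects step toggles", {
  ref <- simulate_reference(n_types = 3, n_genes = 60, cells_per_type = 80,
                            n_markers = 10, seed = 41)
  m <- labeled_cgm(as.matrix(ref$counts), ref$cell_type)
  cfg <- workflow_config(seed = 3, resolution = 1)
  l1 <- run_workflow(m, cfg)
  l2 <- run_workflow(m, cfg)
  expect_identical(as.integer(l1), as.integer(l2))
  # pearson residuals force the log step off
  cfg2 <- workflow_config(normalization = "pearson_residuals",
                          log_transform = TRUE)
  expect_false(cfg2$log_transform)
  expect_error(run_workflow(m, workflow_config(n_pcs = 1000)), "n_pcs")
})

test_that("one-step perturbations are scored against the base partition", {
  ref <- simulate_reference(n_types = 3, n_genes = 60, cells_per_type = 80,
                            n_markers = 10, seed = 43)
  m <- labeled_cgm(as.matrix(ref$counts), ref$cell_type)
  cfg <- workflow_config(seed = 5)
  base <- run_workflow(m, cfg)
  # toggling an already-disabled step re-runs identically
  noop <- perturb_and_score(m, cfg, "hvf_selection", value = FALSE,
                            base_labels = base)
  expect_equal(noop$comparison$ari, 1)
  expect_equal(noop$comparison$vi, 0)
  # disabling normalization on a library-size-spread matrix changes clusters
  spread <- as.matrix(ref$counts)
  set.seed(9)
  fac <- sample(c(1L, 100L), nrow(spread), TRUE)
  spread <- spread * fac
  ms <- labeled_cgm(spread, ref$cell_type)
  base_s <- run_workflow(ms, cfg)
  pert <- perturb_and_score(ms, cfg, "normalization", value = "none",
                            base_labels = base_s)
  expect_lt(pert$comparison$ari, 1)
})
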