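test_that("negative markers match an exhaustive per-type fraction scan", {
  set.seed(21)
  counts <- random_counts(200, 30, seed = 21, lambda = 0.4)
  counts[, 1] <- 0  # silent gene: negative marker for every type
  types <- sample(c("A", "B", "C"), 200, replace = TRUE)
  ref <- reference_profile(counts, types)
  mk <- find_negative_markers(ref, max_expressing_fraction = 0.2)
  # brute-force scan
  for (g in colnames(counts)) {
    for (ty in c("A", "B", "C")) {
      frac <- mean(counts[types == ty, g] > 0)
      expect_equal(any(mk$pairs$gene == g & mk$pairs$cell_type == ty),
                   frac < 0.2)
    }
  }
  expect_setequal(mk$neg_types[["g001"]], c("A", "B", "C"))
  one_type <- reference_profile(counts, rep("A", 200))
  expect_error(find_negative_markers(one_type), "two cell types")
})

test_that("balanced expression normalises per-type means to row sums of 1", {
  counts <- matrix(c(1, 1, 4, 4,   # gene x: means A=1, B=4
                     2, 2, 0, 0),  # gene y: only in A
                   nrow = 4,
                   dimnames = list(paste0("c", 1:4), c("x", "y")))
  be <- balanced_expression(counts, c("A", "A", "B", "B"))
  expect_equal(be$Xbar["x", ], c(A = 0.2, B = 0.8))
  expect_equal(be$Xbar["y", ], c(A = 1, B = 0))
  # random matrix: direct formula evaluation
  rc <- random_counts(60, 12, seed = 8)
  ty <- rep(c("A", "B", "C", "D", "E"), each = 12)
  be2 <- balanced_expression(rc, ty)
  for (g in colnames(rc)) {
    means <- sapply(sort(unique(ty)), function(tt) mean(rc[ty == tt, g]))
    expect_equal(be2$Xbar[g, ], means / sum(means))
  }
  expect_true(all(abs(rowSums(be2$Xbar) - 1) < 1e-12))
})

test_that("NMP follows the two-branch formula on a constructed example", {
  # single pair (g1, A); spatial means {A:1, B:4}; reference {A:0, B:5}
  sp <- matrix(c(1, 1, 4, 4, 9, 9, 9, 9), nrow = 4,
               dimnames = list(paste0("s", 1:4), c("g1", "g2")))
  ref_counts <- matrix(c(0, 0, 5, 5, 9, 9, 9, 9), nrow = 4,
                       dimnames = list(paste0("r", 1:4), c("g1", "g2")))
  ref <- reference_profile(ref_counts, c("A", "A", "B", "B"))
  markers <- list(pairs = data.frame(gene = "g1", cell_type = "A",
                                     stringsAsFactors = FALSE))
  res <- negative_marker_purity(sp, ref, markers,
                                sp_cell_type = c("A", "A", "B", "B"))
  expect_equal(res$x_neg_sp, 0.2)
  expect_equal(res$x_neg_sc, 0)
  expect_equal(res$nmp, 0.8)
  # equality case: identical matrices hit the "otherwise" branch exactly
  res2 <- negative_marker_purity(ref_counts, ref, markers,
                                 sp_cell_type = ref$cell_type)
  expect_equal(res2$nmp, 1)
})

test_that("NMP equals the loop-oracle on random matrices and is <= 1", {
  for (s in 1:8) {
    n <- 40 + s
    ng <- 15
    counts <- random_counts(n, ng, seed = 100 + s, lambda = 1)
    types <- sample(LETTERS[1:4], n, replace = TRUE)
    ref <- reference_profile(random_counts(n, ng, seed = 200 + s, lambda = 1),
                             sample(LETTERS[1:4], n, replace = TRUE))
    mk <- find_negative_markers(ref, max_expressing_fraction = 0.3)
    if (nrow(mk$pairs) == 0) next
    got <- suppressWarnings(
      negative_marker_purity(counts, ref, mk, sp_cell_type = types))
    want <- oracle_nmp(counts, types, as.matrix(ref$counts), ref$cell_type,
                       mk$pairs)
    expect_equal(got$nmp, want, tolerance = 1e-12)
    expect_lte(got$nmp, 1)
  }
})

test_that("NMP is invariant to duplicating every cell", {
  ref <- simulate_reference(n_types = 3, n_genes = 40, cells_per_type = 60,
                            n_markers = 6, seed = 5)
  mk <- find_negative_markers(ref)
  sp <- as.matrix(ref$counts)
  ty <- ref$cell_type
  base <- negative_marker_purity(sp, ref, mk, sp_cell_type = ty)$nmp
  dup <- rbind(sp, sp)
  rownames(dup) <- paste0("d", seq_len(nrow(dup)))
  dup_res <- negative_marker_purity(dup, ref, mk,
                                    sp_cell_type = c(ty, ty))$nmp
  expect_equal(dup_res, base)
})

test_that("scaled NMP fixes raw = 1 and raw = baseline, reproducibly", {
  ref <- simulate_reference(n_types = 3, n_genes = 40, cells_per_type = 60,
                            n_markers = 6, seed = 9)
  mk <- find_negative_markers(ref)
  sp <- labeled_cgm(as.matrix(ref$counts), ref$cell_type)
  s <- scaled_nmp(sp, ref, mk, n_perm = 10, seed = 1)
  expect_equal(s$raw, 1)
  expect_equal(s$scaled, 1)  # fixed point of the affine map
  expect_lt(s$baseline, 1)
  # same seed twice: identical baseline
  s2 <- scaled_nmp(sp, ref, mk, n_perm = 10, seed = 1)
  expect_equal(s2$baseline, s$baseline)
  # different seed: different permutation stream
  s3 <- scaled_nmp(sp, ref, mk, n_perm = 10, seed = 2)
  expect_false(identical(s3$baseline, s$baseline))
})

test_that("raw NMP degrades as mis-segmentation mixing increases", {
  ref <- simulate_reference(n_types = 4, n_genes = 60, cells_per_type = 100,
                            n_markers = 8, seed = 13)
  sp <- labeled_cgm(as.matrix(ref$counts), ref$cell_type)
  mk <- find_negative_markers(ref)
  nmps <- sapply(c(0, 0.25, 0.5), function(mix) {
    mixed <- simulate_missegmentation(sp, f = 0.4, mix = mix, seed = 31)$m
    negative_marker_purity(mixed, ref, mk)$nmp
  })
  expect_equal(nmps[1], 1)
  expect_true(all(diff(nmps) < 0))
})

test_that("non-coexpressed pairs equal the exhaustive pairwise scan", {
  counts <- random_counts(80, 12, seed = 44, lambda = 0.3)
  ref <- reference_profile(counts, rep(c("A", "B"), 40))
  pr <- find_noncoexpressed_pairs(ref, coexpr_fraction_max = 0.05)
  for (i in 1:(ncol(counts) - 1)) {
    for (j in (i + 1):ncol(counts)) {
      frac <- mean(counts[, i] > 0 & counts[, j] > 0)
      g1 <- colnames(counts)[i]; g2 <- colnames(counts)[j]
      expect_equal(any(pr$pairs$gene1 == g1 & pr$pairs$gene2 == g2),
                   frac < 0.05)
    }
  }
  expect_error(find_noncoexpressed_pairs(counts[, 1, drop = FALSE]),
               "two genes")
})

test_that("NCP hits its bounds and counts pairs correctly", {
  # 3 cells; pairs (a,b) never co-positive, (a,c) always co-positive
  counts <- matrix(c(1, 1, 1,  0, 0, 0,  1, 1, 1), nrow = 3,
                   dimnames = list(paste0("c", 1:3), c("a", "b", "c")))
  pairs <- structure(list(
    pairs = data.frame(gene1 = c("a", "a"), gene2 = c("b", "c"),
                       stringsAsFactors = FALSE),
    coexpr_fraction_max = 0.005), class = "noncoexpressed_pairs")
  res <- ncp(counts, pairs)
  expect_equal(res$ncp, 0.5)
  expect_equal(res$n_pairs, 2)
  # self-consistency: reference against itself scores 1
  ref <- simulate_reference(n_types = 3, n_genes = 45, cells_per_type = 80,
                            n_markers = 8, seed = 3)
  pr <- find_noncoexpressed_pairs(ref)
  self <- ncp(as.matrix(ref$counts), pr)
  expect_equal(self$ncp, 1)
  # pairs with genes outside the panel are dropped and counted
  sub <- as.matrix(ref$counts)[, 1:20]
  res2 <- ncp(sub, pr)
  expect_equal(res2$n_pairs + res2$n_dropped, nrow(pr$pairs))
})
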