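test_that("reference type filter applies the strictly-more-than-ten rule", {
  counts <- random_counts(36, 5, seed = 1)
  types <- c(rep("small", 10), rep("edge", 11), rep("big", 15))
  ref <- reference_profile(counts, types)
  filt <- filter_reference(ref)
  expect_setequal(unique(filt$cell_type), c("edge", "big"))
  # brute force survivor count
  expect_equal(nrow(filt$counts), sum(table(types)[table(types) >= 11]))
  big <- reference_profile(random_counts(40, 5, seed = 2),
                           rep(c("a", "b"), 20))
  expect_equal(nrow(filter_reference(big)$counts), 40)
  expect_error(filter_reference(ref, min_cells = 100), "min_cells")
})

test_that("panel selection recovers designated markers deterministically", {
  ref <- simulate_reference(n_types = 3, n_genes = 80, cells_per_type = 120,
                            n_markers = 10, seed = 0)
  panel <- select_panel(ref, n_top = 10)
  truem <- unlist(attr(ref, "markers"))
  expect_gte(mean(truem %in% panel$features), 0.9)
  expect_identical(panel$features, select_panel(ref, n_top = 10)$features)
  # constructed disjoint exclusive markers: panel is exactly their union
  counts <- cbind(
    matrix(c(rep(9L, 10), rep(0L, 10)), 20, 2,
           dimnames = list(NULL, c("mA1", "mA2"))),
    matrix(c(rep(0L, 10), rep(9L, 10)), 20, 2,
           dimnames = list(NULL, c("mB1", "mB2"))))
  rownames(counts) <- paste0("c", 1:20)
  ref2 <- reference_profile(counts, rep(c("A", "B"), each = 10))
  p2 <- select_panel(ref2, n_top = 2)
  expect_setequal(p2$features, c("mA1", "mA2", "mB1", "mB2"))
  # n_top beyond the gene count keeps everything, with a warning
  expect_warning(p3 <- select_panel(ref2, n_top = 99), "fewer genes")
  expect_setequal(p3$features, colnames(counts))
})

test_that("efficiency resampling preserves expectations and zeros", {
  m <- random_counts(2000, 4, seed = 6, lambda = 5)
  m[, 4] <- 0L
  e <- c(g001 = 1, g002 = 0.5, g003 = 1.5, g004 = 1)
  out <- as.matrix(apply_efficiency(m, e, seed = 2))
  expect_true(all(out[, 4] == 0))  # Poisson(0) stays 0
  for (g in 1:3) {
    mu <- e[g] * mean(m[, g])
    se <- sd(out[, g]) / sqrt(nrow(m))
    expect_lt(abs(mean(out[, g]) - mu), 3 * se + 3 * sqrt(mu / nrow(m)))
  }
  # reproducible under the same seed
  expect_identical(as.matrix(apply_efficiency(m, e, seed = 2)), out)
  expect_error(apply_efficiency(m, c(g001 = -1), 1), "positive")
})

test_that("non-specific noise hits its target share with uniform genes", {
  m <- random_counts(500, 40, seed = 10, lambda = 5)
  expect_identical(as.matrix(add_nonspecific_noise(m, 0, seed = 1)), m)
  out <- as.matrix(add_nonspecific_noise(m, 0.1, seed = 1))
  added <- sum(out) - sum(m)
  share <- added / sum(out)
  se <- sqrt(0.1 * 0.9 / sum(out))
  expect_lt(abs(share - 0.1), 5 * se + 0.01)
  # noise gene distribution is uniform (chi-square at alpha = 0.01)
  per_gene <- colSums(out - m)
  expect_gt(chisq.test(per_gene)$p.value, 0.01)
  # control features can take their own rate
  p <- make_panel(c(colnames(m), "NegControlProbe_1"))
  m2 <- cbind(m, NegControlProbe_1 = 0L)
  out2 <- as.matrix(add_nonspecific_noise(m2, 0, seed = 3,
                                          control_features = "NegControlProbe_1",
                                          control_rho = 0.05))
  expect_gt(sum(out2[, "NegControlProbe_1"]), 0)
  expect_equal(out2[, colnames(m)], m2[, colnames(m)])
})

test_that("mis-segmentation conserves totals and contaminates the listed cells", {
  m <- random_counts(60, 20, seed = 15, lambda = 3)
  expect_identical(as.matrix(simulate_missegmentation(m, 0, 0.5, 1)$m), m)
  expect_identical(as.matrix(simulate_missegmentation(m, 0.5, 0, 1)$m), m)
  res <- simulate_missegmentation(m, 0.3, 0.25, seed = 4)
  out <- as.matrix(res$m)
  expect_equal(sum(out), sum(m))  # conservation, always
  expect_equal(nrow(res$contaminated), round(0.3 * 60))
  # reads only move along the recorded (partner -> cell) edges
  gains <- rowSums(out) - rowSums(m)
  touched <- union(res$contaminated$cell, res$contaminated$partner)
  expect_true(all(gains[setdiff(rownames(m), touched)] == 0))
  expect_gt(max(gains[res$contaminated$cell]), 0)
  expect_error(simulate_missegmentation(m[1, , drop = FALSE], 0.5, 0.5, 1),
               "two cells")
})

test_that("the NB reference is seeded, labeled and Poisson in the zero-dispersion limit", {
  r1 <- simulate_reference(n_types = 2, n_genes = 30, cells_per_type = 50,
                           n_markers = 5, seed = 12)
  r2 <- simulate_reference(n_types = 2, n_genes = 30, cells_per_type = 50,
                           n_markers = 5, seed = 12)
  expect_identical(as.matrix(r1$counts), as.matrix(r2$counts))
  expect_equal(sort(unique(r1$cell_type)), c("type1", "type2"))
  # mean_expr is recomputable from counts exactly
  for (ty in unique(r1$cell_type)) {
    expect_equal(r1$mean_expr[, ty],
                 colMeans(as.matrix(r1$counts[r1$cell_type == ty, ])))
  }
  pois <- simulate_reference(n_types = 1, n_genes = 40, cells_per_type = 800,
                             n_markers = 0, dispersion = 0, seed = 3,
                             baseline_range = c(5, 5))
  x <- as.matrix(pois$counts)
  vm <- apply(x, 2, var) / colMeans(x)
  expect_lt(abs(mean(vm) - 1), 0.05)
})

test_that("spatial fixtures honour their declared geometry", {
  cfg <- sim_config(n_cells = 12, n_types = 2, cell_radius = 10,
                    nucleus_radius = 5, n_background = 800, seed = 2)
  fx <- generate_spatial_fixture(cfg)
  tt <- fx$transcripts
  cells <- fx$truth$cells
  # assigned reads lie within R of their cell; nuclear reads within r
  idx <- match(tt$cell_id, cells$cell_id)
  d <- sqrt((tt$x - cells$x[idx])^2 + (tt$y - cells$y[idx])^2)
  expect_true(all(d[!is.na(tt$cell_id)] <= 10 + 1e-9, na.rm = TRUE))
  expect_true(all(d[tt$overlaps_nucleus %in% TRUE] <= 5 + 1e-9, na.rm = TRUE))
  # background reads lie outside every cell disk
  bg <- is.na(tt$cell_id)
  dmin <- sapply(which(bg), function(k)
    min(sqrt((tt$x[k] - cells$x)^2 + (tt$y[k] - cells$y)^2)))
  expect_true(all(dmin > 10))
  # label images agree with geometry: nucleus pixels sit inside cell pixels
  expect_true(all(fx$cells[fx$nuclei > 0] == fx$nuclei[fx$nuclei > 0]))
  # determinism
  fx2 <- generate_spatial_fixture(cfg)
  expect_identical(fx2$transcripts$x, tt$x)
  # qv mixture leaves the quality filter something to do
  expect_gt(mean(tt$qv > 20), 0.5)
  expect_lt(mean(tt$qv > 20), 0.99)
  expect_error(sim_config(n_cells = 5, n_types = 1),
               "seed")
})

test_that("two-layer fixtures stack partner cells with disjoint signatures", {
  fx <- generate_spatial_fixture(sim_config(n_cells = 9, n_types = 1,
                                            two_layer = TRUE,
                                            n_background = 200, seed = 6))
  cells <- fx$truth$cells
  expect_true(any(cells$layer == 2))
  partners <- cells[cells$layer == 2, ]
  # each partner shares xy with a layer-1 cell in the overlap strip
  for (k in seq_len(nrow(partners))) {
    match_row <- cells[cells$layer == 1 & cells$x == partners$x[k] &
                       cells$y == partners$y[k], ]
    expect_equal(nrow(match_row), 1)
    expect_true(match_row$cell_id %in% fx$truth$overlap_nuclei)
  }
  # z separation between the layers
  tt <- fx$transcripts
  lay <- cells$layer[match(tt$cell_id, cells$cell_id)]
  expect_lt(max(tt$z[lay == 1], na.rm = TRUE),
            min(tt$z[lay == 2], na.rm = TRUE))
  # layer-2 types draw from the z gene blocks
  z_reads <- tt$gene[!is.na(tt$cell_id) & lay == 2]
  expect_true(all(grepl("^(Z|D)", z_reads)))
})
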