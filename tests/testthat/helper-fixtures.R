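# in-code fixtures shared across tests

tiny_transcripts <- function() {
  transcript_table(data.frame(
    x = c(1, 2, 3, 4, 10),
    y = c(1, 2, 3, 4, 10),
    z = c(0, 1, 2, 3, 4),
    gene = c("gA", "gA", "gB", "gB", "gA"),
    qv = c(35, 25, 18, 40, 30),
    cell_id = c("c1", "c1", "c2", "c2", NA),
    overlaps_nucleus = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  ))
}

random_transcripts <- function(n, seed, genes = paste0("g", 1:5),
                               cells = c(paste0("c", 1:10), NA)) {
  set.seed(seed)
  transcript_table(data.frame(
    x = runif(n, 0, 100), y = runif(n, 0, 100), z = runif(n, 0, 10),
    gene = sample(genes, n, replace = TRUE),
    qv = runif(n, 0, 40),
    cell_id = sample(cells, n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# small labeled count matrix with named dims
random_counts <- function(n_cells, n_genes, seed, lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("g%03d", seq_len(n_genes))))
  m
}

labeled_cgm <- function(counts, types) {
  cell_gene_matrix(counts, data.frame(cell_id = rownames(counts),
                                      cell_type = types,
                                      stringsAsFactors = FALSE))
}

# direct transliteration of the balanced-expression / NMP equations,
# written as plain nested loops to stay independent of the package path
oracle_nmp <- function(sp_counts, sp_types, ref_counts, ref_types, pairs) {
  balanced <- function(counts, types, gene, type) {
    counts <- as.matrix(counts)
    all_types <- sort(unique(types))
    means <- sapply(all_types, function(tt)
      mean(counts[types == tt, gene]))
    if (sum(means) == 0) return(NA_real_)
    unname(means[type] / sum(means))
  }
  x_sp <- x_sc <- 0
  for (k in seq_len(nrow(pairs))) {
    x_sp <- x_sp + balanced(sp_counts, sp_types, pairs$gene[k], pairs$cell_type[k])
    x_sc <- x_sc + balanced(ref_counts, ref_types, pairs$gene[k], pairs$cell_type[k])
  }
  x_sp <- x_sp / nrow(pairs)
  x_sc <- x_sc / nrow(pairs)
  if (x_sp > x_sc) 1 - (x_sp - x_sc) else 1
}
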