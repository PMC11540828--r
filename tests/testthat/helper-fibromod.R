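# Shared fixtures and small independent oracles used across test files.

# Adjusted Rand index from the contingency table (independent of any
# clustering package; used to cross-check mclust::adjustedRandIndex).
ari_from_table <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# Gene x sample matrix with correlated blocks planted on shared factors.
# block_cor is the loading of every block gene on its factor.
make_block_matrix <- function(block_sizes, n_noise, n_samples,
                              block_cor = 0.9, seed = 42) {
  set.seed(seed)
  n_genes <- sum(block_sizes) + n_noise
  mat <- matrix(rnorm(n_genes * n_samples) * sqrt(1 - block_cor^2),
                n_genes, n_samples)
  row <- 1
  truth <- rep("0", n_genes)
  for (b in seq_along(block_sizes)) {
    f <- rnorm(n_samples)
    idx <- row:(row + block_sizes[b] - 1)
    mat[idx, ] <- mat[idx, ] + block_cor * matrix(f, length(idx),
                                                  n_samples,
                                                  byrow = TRUE)
    truth[idx] <- as.character(b)
    row <- row + block_sizes[b]
  }
  rownames(mat) <- sprintf("g%03d", seq_len(n_genes))
  colnames(mat) <- sprintf("s%03d", seq_len(n_samples))
  list(mat = mat, truth = setNames(truth, rownames(mat)))
}

# small truth-labelled module structure for projection tests
make_truth_modules <- function(config = simulation_config()) {
  labels <- rep("0", config$n_genes)
  names(labels) <- sprintf("g%04d", seq_len(config$n_genes))
  profiles <- character(0)
  i <- 1
  for (p in config$module_plans) {
    labels[i:(i + p$size - 1)] <- p$module_id
    profiles[p$module_id] <- p$phase_profile
    i <- i + p$size
  }
  list(labels = labels, profiles = profiles)
}

best_jaccard <- function(truth_genes, det_labels) {
  best <- 0
  for (d in setdiff(unique(det_labels), "0")) {
    dg <- names(det_labels)[det_labels == d]
    j <- length(intersect(truth_genes, dg)) /
      length(union(truth_genes, dg))
    best <- max(best, j)
  }
  best
}
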