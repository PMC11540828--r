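test_that("correlation matrix matches the textbook formula", {
  set.seed(1)
  m <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("g%d", 1:10),
                              sprintf("s%d", 1:8)))
  m <- rbind(m, dup = m[1, ], neg = -m[2, ])
  cc <- correlation_matrix(m)
  expect_equal(unname(cc["dup", "g1"]), 1)
  expect_equal(unname(cc["neg", "g2"]), -1)
  brute <- function(u, v)
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(cc["g3", "g7"], brute(m["g3", ], m["g7", ]),
               tolerance = 1e-12)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 12))

  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
  expect_error(correlation_matrix(rbind(m, const = rep(1, 8))),
               "zero-variance")
})

test_that("soft adjacency is the unsigned power of correlation", {
  cc <- matrix(c(1, 0.5, 0, 0.5, 1, -1, 0, -1, 1), 3, 3)
  a <- soft_adjacency(cc, 4)
  expect_equal(a[1, 2], 0.0625)
  expect_equal(a[2, 3], 1)        # |-1|^4, unsigned network
  expect_equal(a[1, 3], 0)
  expect_equal(unname(diag(a)), rep(0, 3))
  expect_error(soft_adjacency(cc, 0.5), "power")
})

test_that("scale-free fit recovers a constructed power-law degree sequence", {
  k_levels <- seq(5, 95, by = 10)
  counts <- round(500 * (k_levels / k_levels[1])^-2)
  k <- rep(k_levels, counts)
  a <- outer(k, k) / sum(k)
  diag(a) <- 0
  fit <- scale_free_fit(a)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(fit$slope, 0)

  expect_warning(flat <- scale_free_fit(matrix(1, 5, 5) - diag(5)),
                 "degenerate")
  expect_equal(flat$r_squared, 0)

  set.seed(2)
  cc <- cor(matrix(rnorm(30 * 10), 10, 30))
  scan <- pick_soft_threshold(cc, powers = c(1, 2, 4, 6))
  expect_equal(scan$power, c(1, 2, 4, 6))
  expect_equal(ncol(scan), 3)
})

test_that("topological overlap equals the brute-force triple loop", {
  clique <- matrix(1, 3, 3) - diag(3)
  expect_equal(topological_overlap(clique)[1, 2], 1)

  iso <- diag(0, 4)           # no edges at all
  expect_equal(topological_overlap(iso)[1, 2], 0)

  set.seed(3)
  n <- 20
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  tom <- topological_overlap(a)
  k <- colSums(a)
  brute <- matrix(1, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    s <- 0
    for (u in 1:n) s <- s + a[i, u] * a[u, j]
    brute[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  expect_equal(tom, brute, tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1))

  expect_error(topological_overlap(a - 1), "non-negative")
  expect_error(topological_overlap(a + diag(n)), "zero diagonal")
})

test_that("average-linkage clustering follows hand-computed UPGMA heights", {
  d3 <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- cluster_genes(d3)
  expect_equal(tree$height, c(0.1, 0.9))

  blocks <- matrix(0.8, 6, 6)
  blocks[1:3, 1:3] <- 0; blocks[4:6, 4:6] <- 0  # identical genes
  dimnames(blocks) <- list(letters[1:6], letters[1:6])
  tb <- cluster_genes(blocks)
  expect_equal(tb$height[1:4], rep(0, 4))

  dn <- d3; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(cluster_genes(dn), "non-finite")

  set.seed(4)
  m <- matrix(runif(100), 10, 10)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:10], letters[1:10])
  perm <- sample(10)
  t1 <- cluster_genes(m)
  t2 <- cluster_genes(m[perm, perm])
  expect_equal(sort(t1$height), sort(t2$height))
  p1 <- cutree(t1, 3)[letters[1:10]]
  p2 <- cutree(t2, 3)[letters[1:10]]
  expect_equal(ari_from_table(p1, p2), 1)  # same partition, any labels
})

test_that("tree cutting recovers planted blocks and filters small branches", {
  bm <- make_block_matrix(c(50, 50), 100, 80, block_cor = 0.9)
  cc <- correlation_matrix(bm$mat)
  diss <- 1 - topological_overlap(soft_adjacency(cc, 4))
  diag(diss) <- 0
  labels <- cut_tree_dynamic(cluster_genes(diss), network_params())
  mods <- setdiff(unique(labels), "0")
  expect_length(mods, 2)
  noise_genes <- names(bm$truth)[bm$truth == "0"]
  expect_gte(mean(labels[noise_genes] == "0"), 0.8)
  for (m in mods) {                       # branches are block-pure
    dg <- names(labels)[labels == m]
    expect_gte(max(table(bm$truth[dg])) / length(dg), 0.9)
  }
  for (b in c("1", "2")) {                # and capture the block cores
    block_genes <- names(bm$truth)[bm$truth == b]
    expect_gte(best_jaccard(block_genes, labels), 0.5)
  }
  # labels renumbered by decreasing size
  sz <- table(labels[labels != "0"])
  expect_true(all(diff(as.integer(sz[order(as.integer(names(sz)))])) <= 0))

  # the full detection pipeline recovers the complete blocks
  ms <- detect_modules(bm$mat, network_params())
  for (b in c("1", "2")) {
    block_genes <- names(bm$truth)[bm$truth == b]
    expect_gte(best_jaccard(block_genes, ms$labels), 0.9)
  }

  # no branch reaching the minimum size leaves everything unassigned
  bm29 <- make_block_matrix(29, 0, 40, block_cor = 0.95)
  cc29 <- correlation_matrix(bm29$mat)
  d29 <- 1 - topological_overlap(soft_adjacency(cc29, 4))
  diag(d29) <- 0
  expect_warning(l29 <- cut_tree_dynamic(cluster_genes(d29),
                                         network_params()),
                 "unassigned")
  expect_true(all(l29 == "0"))
})

test_that("duplicating every gene doubles module sizes without changing structure", {
  bm <- make_block_matrix(c(40, 40), 20, 30, block_cor = 0.9)
  m2 <- rbind(bm$mat, bm$mat)
  rownames(m2) <- c(rownames(bm$mat), paste0(rownames(bm$mat), "_dup"))
  ms <- detect_modules(m2, network_params())
  for (b in c("1", "2")) {
    genes <- names(bm$truth)[bm$truth == b]
    both <- c(genes, paste0(genes, "_dup"))
    expect_gte(best_jaccard(both, ms$labels), 0.9)
  }
})

test_that("eigengenes agree with a dense PCA oracle and orient consistently", {
  # identical genes: eigengene is the standardized common profile
  prof <- rnorm(20)
  m <- matrix(rep(prof, each = 4), 4, 20,
              dimnames = list(letters[1:4], sprintf("s%d", 1:20)))
  m <- m + matrix(rnorm(80, sd = 1e-9), 4, 20)
  eg <- compute_eigengenes(m, setNames(rep("1", 4), letters[1:4]))
  expect_equal(eg$variance_explained[["ME1"]], 1, tolerance = 1e-6)
  zp <- (prof - mean(prof)) / sd(prof)
  cosine <- abs(sum(eg$eigengenes[1, ] * zp) /
                  sqrt(sum(zp^2)))
  expect_equal(cosine, 1, tolerance = 1e-6)
  expect_equal(sum(eg$eigengenes[1, ]^2), 1, tolerance = 1e-12)

  # perfectly anticorrelated pair: first-gene-positive tie break
  x <- rnorm(15)
  pair <- rbind(g1 = x, g2 = -x + 1)
  colnames(pair) <- sprintf("s%d", 1:15)
  ep <- compute_eigengenes(pair, setNames(c("1", "1"), c("g1", "g2")))
  expect_equal(ep$variance_explained[["ME1"]], 1, tolerance = 1e-10)
  expect_gt(cor(ep$eigengenes[1, ], pair["g1", ]), 0)

  # random module versus brute-force eigendecomposition
  set.seed(5)
  r <- matrix(rnorm(40 * 25), 40, 25,
              dimnames = list(sprintf("g%d", 1:40),
                              sprintf("s%d", 1:25)))
  er <- compute_eigengenes(r, setNames(rep("1", 40), rownames(r)))
  z <- t(scale(t(r)))
  ev <- eigen(crossprod(z))$vectors[, 1]
  expect_gte(abs(sum(er$eigengenes[1, ] * ev)), 1 - 1e-10)
  # orientation invariant: mean kME non-negative
  expect_gte(mean(cor(t(r), er$eigengenes[1, ])), 0)
})

test_that("module merging fuses split blocks and respects the threshold", {
  bm <- make_block_matrix(60, 60, 40, block_cor = 0.9, seed = 6)
  labels <- bm$truth
  labels[labels == "1"][1:30] <- "2"  # artificial split of one block
  labels[labels == "0"] <- "0"
  merged <- merge_modules(bm$mat, labels, 0.75)
  expect_length(setdiff(unique(merged$labels), "0"), 1)

  two <- make_block_matrix(c(50, 50), 0, 60, block_cor = 0.9, seed = 7)
  kept <- merge_modules(two$mat, two$truth, 0.75)
  expect_length(setdiff(unique(kept$labels), "0"), 2)
  C <- abs(cor(t(kept$eigengenes)))
  expect_lte(max(C[upper.tri(C)]), 0.75)
})

test_that("hub genes maximize kME with lexicographic tie-breaking", {
  loads <- c(A = 0.9, B = 0.5, C = 0.5, D = 0.5, E = 0.5, F = 0.5)
  wins <- 0
  for (s in 1:50) {
    set.seed(s)
    f <- rnorm(100)
    m <- outer(loads, f) +
      matrix(rnorm(length(loads) * 100, sd = 0.5), length(loads), 100)
    rownames(m) <- names(loads)
    colnames(m) <- sprintf("s%d", 1:100)
    lab <- setNames(rep("1", length(loads)), names(loads))
    eg <- compute_eigengenes(m, lab)
    hb <- hub_genes(m, lab, eg$eigengenes)
    if (hb$hubs$hub_gene == "A") wins <- wins + 1
  }
  expect_gte(wins, 48)

  # exact tie: duplicated gene values, smaller id wins
  x <- rnorm(30)
  tied <- rbind(a = x, b = x, c = rnorm(30))
  colnames(tied) <- sprintf("s%d", 1:30)
  lab <- setNames(rep("1", 3), c("a", "b", "c"))
  eg <- compute_eigengenes(tied, lab)
  hb <- hub_genes(tied, lab, eg$eigengenes)
  expect_equal(hb$hubs$hub_gene, "a")
  expect_equal(nrow(hb$kme), 3)

  # a gene whose profile IS the dominant pattern has kME ~ 1
  set.seed(9)
  f2 <- rnorm(40)
  m2 <- rbind(hub = f2,
              g2 = 0.6 * f2 + rnorm(40, sd = 0.1),
              g3 = -0.5 * f2 + rnorm(40, sd = 0.1))
  colnames(m2) <- sprintf("s%d", 1:40)
  lab2 <- setNames(rep("1", 3), rownames(m2))
  eg2 <- compute_eigengenes(m2, lab2)
  hb2 <- hub_genes(m2, lab2, eg2$eigengenes)
  expect_equal(hb2$hubs$hub_gene, "hub")
  expect_gte(abs(hb2$hubs$kme), 0.99)
})

test_that("zero-variance genes are filtered with a manifest", {
  bm <- make_block_matrix(40, 10, 30)
  m <- rbind(bm$mat, flat1 = rep(2, 30), flat2 = rep(0, 30))
  filt <- drop_zero_variance(m)
  expect_equal(filt$dropped, c("flat1", "flat2"))
  expect_equal(nrow(filt$mat), 50)
})
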