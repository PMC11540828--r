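#' Network construction parameters
#'
#' @param power soft-threshold exponent beta applied to |correlation|
#'   (default 4, the value used for the bleomycin network).
#' @param min_module_size smallest branch accepted as a module
#'   (default 30).
#' @param merge_cor_threshold eigengene correlation above which two
#'   modules are merged (default 0.75).
#' @param cut_method how the dendrogram cut height is chosen:
#'   `"adaptive"` (default) scans candidate heights and uses the one
#'   producing the largest number of branches of at least
#'   `min_module_size` genes (ties broken towards the lowest height);
#'   `"quantile"` cuts statically at `cut_height_quantile` of the merge
#'   heights.
#' @param cut_height_quantile quantile of merge heights for the static
#'   cut (default 0.99).
#' @param use_tom cluster on topological-overlap dissimilarity (default)
#'   rather than `1 - |cor|^power`.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @param ve_gate minimum ratio between a candidate branch's eigengene
#'   variance explained and the Marchenko-Pastur expectation
#'   `(1 + sqrt(m/n))^2 / m` for `m` independent genes over `n`
#'   samples; branches below the gate are not accepted as modules (they
#'   are indistinguishable from clustered noise).  Set to 0 to disable.
#' @param pam_kme_threshold after cutting and merging, unassigned genes
#'   whose best absolute module membership (|kME|) reaches this value
#'   are attached to the corresponding module (the partitioning-style
#'   refinement of dynamic tree cutting); set to `NA` to disable.
#' @param candidate_powers powers scanned by [pick_soft_threshold()].
#' @return object of class `network_params`.
#' @export
network_params <- function(power = 4,
                           min_module_size = 30,
                           merge_cor_threshold = 0.75,
                           cut_method = c("adaptive", "quantile"),
                           cut_height_quantile = 0.99,
                           use_tom = TRUE,
                           cor_method = c("pearson", "spearman"),
                           ve_gate = 2.0,
                           pam_kme_threshold = 0.26,
                           candidate_powers = c(1:10, 12, 14, 16)) {
  .assert_scalar_number(power, "power", lower = 1)
  .assert_scalar_number(min_module_size, "min_module_size", lower = 2,
                        integer = TRUE)
  .assert_scalar_number(merge_cor_threshold, "merge_cor_threshold",
                        lower = 1e-8, upper = 1 - 1e-8)
  .assert_scalar_number(cut_height_quantile, "cut_height_quantile",
                        lower = 1e-8, upper = 1 - 1e-8)
  structure(list(power = power,
                 min_module_size = as.integer(min_module_size),
                 merge_cor_threshold = merge_cor_threshold,
                 cut_method = match.arg(cut_method),
                 cut_height_quantile = cut_height_quantile,
                 use_tom = isTRUE(use_tom),
                 cor_method = match.arg(cor_method),
                 ve_gate = ve_gate,
                 pam_kme_threshold = pam_kme_threshold,
                 candidate_powers = candidate_powers),
            class = "network_params")
}

#' Drop zero-variance genes
#'
#' Genes with no variance across samples carry no correlation
#' information and are removed before network construction; the dropped
#' ids are returned so runs can log them.
#'
#' @param mat genes x samples matrix.
#' @return list with `mat` (filtered matrix) and `dropped` (gene ids).
#' @export
drop_zero_variance <- function(mat) {
  .assert_matrix(mat, "mat")
  v <- .row_vars(mat)
  keep <- v > 0
  list(mat = mat[keep, , drop = FALSE],
       dropped = rownames(mat)[!keep])
}

#' Gene-gene correlation matrix
#'
#' @param mat genes x samples matrix with at least 3 samples and no
#'   zero-variance genes (see [drop_zero_variance()]).
#' @param method correlation method.
#' @return symmetric genes x genes correlation matrix.
#' @export
correlation_matrix <- function(mat, method = c("pearson", "spearman")) {
  .assert_matrix(mat, "mat")
  method <- match.arg(method)
  if (ncol(mat) < 3)
    stop("need at least 3 samples to estimate correlations",
         call. = FALSE)
  v <- .row_vars(mat)
  if (any(v == 0))
    stop("zero-variance genes present; call drop_zero_variance() first",
         call. = FALSE)
  stats::cor(t(mat), method = method)
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted network: `a_ij = |cor_ij|^power`, with a zero
#' diagonal so connectivity sums exclude self-edges.
#'
#' @param cor correlation matrix.
#' @param power exponent beta >= 1.
#' @return adjacency matrix with entries in \[0, 1\], zero diagonal.
#' @export
soft_adjacency <- function(cor, power = 4) {
  .assert_square_symmetric(cor, "cor")
  .assert_scalar_number(power, "power", lower = 1)
  if (max(abs(cor)) > 1 + 1e-8)
    stop("'cor' entries must lie in [-1, 1]", call. = FALSE)
  a <- abs(cor)^power
  diag(a) <- 0
  a
}

#' Scale-free topology fit of a weighted network
#'
#' Bins the connectivity distribution and regresses log10 frequency on
#' log10 mean connectivity per bin.  Returns the signed R^2 (positive
#' when frequency decays with connectivity, the scale-free pattern) and
#' the mean connectivity.  Degenerate networks where all connectivities
#' are equal return R^2 = 0 with a warning.
#'
#' @param adjacency adjacency matrix (zero diagonal).
#' @param n_bins number of connectivity bins.
#' @return list with `r_squared` (signed), `mean_k`, `slope`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  .assert_square_symmetric(adjacency, "adjacency")
  k <- colSums(adjacency)
  if (max(k) - min(k) < 1e-12) {
    warning("degenerate connectivity distribution; R^2 reported as 0")
    return(list(r_squared = 0, mean_k = mean(k), slope = NA_real_))
  }
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  kmid <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0 & kmid > 0
  if (sum(ok) < 3) {
    warning("too few populated connectivity bins; R^2 reported as 0")
    return(list(r_squared = 0, mean_k = mean(k), slope = NA_real_))
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(kmid[ok]))
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  list(r_squared = unname(-sign(slope) * r2), mean_k = mean(k),
       slope = unname(slope))
}

#' Scan candidate soft-threshold powers
#'
#' Computes the scale-free fit index and mean connectivity for each
#' candidate power, the tabular counterpart of choosing the power
#' graphically.
#'
#' @param cor correlation matrix.
#' @param powers candidate exponents.
#' @return data.frame with one row per power: power, r_squared, mean_k.
#' @export
pick_soft_threshold <- function(cor, powers = c(1:10, 12, 14, 16)) {
  rows <- lapply(powers, function(b) {
    f <- suppressWarnings(scale_free_fit(soft_adjacency(cor, b)))
    data.frame(power = b, r_squared = f$r_squared, mean_k = f$mean_k)
  })
  do.call(rbind, rows)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` and `TOM_ii = 1`; the corresponding dissimilarity is
#' `1 - TOM`.  Credits shared neighbourhoods, so module co-members score
#' higher than their direct edge alone.
#'
#' @param adjacency symmetric adjacency with entries in \[0, 1\] and zero
#'   diagonal.
#' @return TOM matrix with entries in \[0, 1\], unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  .assert_square_symmetric(adjacency, "adjacency")
  if (any(adjacency < 0))
    stop("'adjacency' must be non-negative", call. = FALSE)
  if (any(diag(adjacency) != 0))
    stop("'adjacency' must have a zero diagonal", call. = FALSE)
  k <- colSums(adjacency)
  num <- adjacency %*% adjacency + adjacency
  minK <- outer(k, k, pmin)
  tom <- num / (minK + 1 - adjacency)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Average-linkage hierarchical clustering of genes
#'
#' @param dissimilarity square symmetric dissimilarity matrix with zero
#'   diagonal (typically `1 - TOM`).
#' @return an `hclust` tree.
#' @export
cluster_genes <- function(dissimilarity) {
  .assert_square_symmetric(dissimilarity, "dissimilarity")
  if (any(!is.finite(dissimilarity)))
    stop("'dissimilarity' contains non-finite values", call. = FALSE)
  stats::hclust(stats::as.dist(dissimilarity), method = "average")
}

#' Cut a gene dendrogram into modules
#'
#' Cuts the tree at a single height and keeps branches with at least
#' `min_module_size` members as modules; smaller branches are assigned
#' label `"0"` (unassigned).  Module labels are renumbered by decreasing
#' size.  The cut height is chosen per `params$cut_method`: the adaptive
#' method scans all merge heights and picks the lowest height maximizing
#' the number of size-qualified branches (so tightly merged planted
#' blocks are separated before background genes coalesce); the quantile
#' method cuts statically at a fixed quantile of the merge heights.
#'
#' @param tree an `hclust` object from [cluster_genes()].
#' @param params a [network_params()].
#' @return named character vector of module labels per gene (`"0"` =
#'   unassigned).
#' @export
cut_tree_dynamic <- function(tree, params = network_params()) {
  if (!inherits(tree, "hclust"))
    stop("'tree' must be an hclust object", call. = FALSE)
  n <- length(tree$order)
  min_size <- params$min_module_size

  qualified <- function(cl) sum(tabulate(cl) >= min_size)
  if (params$cut_method == "quantile") {
    h <- stats::quantile(tree$height, params$cut_height_quantile,
                         names = FALSE)
    cl <- stats::cutree(tree, h = h)
  } else {
    hs <- sort(unique(tree$height))
    # candidate cuts just above each merge height
    cand <- hs + c(diff(hs) / 2, max(hs[length(hs)] * 1e-6, 1e-12))
    clmat <- stats::cutree(tree, h = cand)
    if (is.null(dim(clmat))) clmat <- matrix(clmat, ncol = 1)
    counts <- vapply(seq_len(ncol(clmat)),
                     function(j) qualified(clmat[, j]), 1L)
    best <- which.max(counts)  # which.max returns the first (lowest) max
    cl <- clmat[, best]
  }

  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  if (!length(big)) {
    warning("no branch reaches min_module_size; all genes unassigned")
    labels <- rep("0", n)
    names(labels) <- tree$labels
    return(labels)
  }
  big <- big[order(-sizes[big], as.integer(big))]
  labels <- rep("0", n)
  for (i in seq_along(big)) labels[cl == as.integer(big[i])] <- as.character(i)
  names(labels) <- tree$labels
  labels
}

# Split fused branches: re-cluster each module's own genes; if the
# branch decomposes into two or more gate-passing sub-branches, replace
# it by them (genes of the branch not in any sub-branch become
# unassigned).  Over-splitting of a genuine module is repaired later by
# the eigengene-correlation merge step.
.split_refine <- function(mat, labels, diss, params) {
  for (pass in 1:3) {
    changed <- FALSE
    next_id <- suppressWarnings(
      max(0L, as.integer(labels), na.rm = TRUE)) + 1L
    for (m in setdiff(unique(labels), "0")) {
      genes <- names(labels)[labels == m]
      if (length(genes) < 2L * params$min_module_size) next
      sub_tree <- cluster_genes(diss[genes, genes, drop = FALSE])
      sub_labels <- suppressWarnings(cut_tree_dynamic(sub_tree, params))
      sub_labels <- .apply_ve_gate(mat[genes, , drop = FALSE],
                                   sub_labels, params$ve_gate)
      found <- setdiff(unique(sub_labels), "0")
      if (length(found) < 2) next
      labels[genes] <- "0"
      for (f in found) {
        labels[names(sub_labels)[sub_labels == f]] <-
          as.character(next_id)
        next_id <- next_id + 1L
      }
      changed <- TRUE
    }
    if (!changed) break
  }
  labels
}

# Global module-membership sweep: every gene is reassigned to the
# module whose eigengene it matches best (|kME|), or unassigned when no
# module reaches the threshold.  Cleans background contamination picked
# up by dendrogram branches and lets split module halves converge so
# the subsequent merge step can fuse them.
.kme_sweep <- function(mat, labels, threshold, iterations = 4L) {
  if (!is.finite(threshold)) return(labels)
  for (i in seq_len(iterations)) {
    mods <- setdiff(unique(labels), "0")
    if (length(mods) < 1) break
    eg <- compute_eigengenes(mat, labels)$eigengenes
    km <- abs(stats::cor(t(mat), t(eg)))
    best <- max.col(km, ties.method = "first")
    new_labels <- ifelse(km[cbind(seq_len(nrow(mat)), best)] >=
                           threshold,
                         sub("^ME", "", rownames(eg))[best], "0")
    names(new_labels) <- rownames(mat)
    # a sweep must not empty a module set entirely
    if (all(new_labels == "0")) break
    # drop modules reduced below viability for eigengene computation
    sz <- table(new_labels[new_labels != "0"])
    for (m in names(sz)[sz < 3]) new_labels[new_labels == m] <- "0"
    if (all(new_labels == "0")) break
    if (identical(new_labels, labels)) { labels <- new_labels; break }
    labels <- new_labels
  }
  labels
}

# Unassign candidate modules whose eigengene explains no more variance
# than expected for clustered independent noise (Marchenko-Pastur).
.apply_ve_gate <- function(mat, labels, gate) {
  if (!is.finite(gate) || gate <= 0) return(labels)
  n <- ncol(mat)
  for (m in setdiff(unique(labels), "0")) {
    genes <- names(labels)[labels == m]
    sz <- length(genes)
    ve <- compute_eigengenes(mat[genes, , drop = FALSE],
                             stats::setNames(rep(m, sz), genes)
                             )$variance_explained
    mp <- (1 + sqrt(sz / n))^2 / sz
    if (ve / mp < gate) labels[labels == m] <- "0"
  }
  labels
}

#' Module eigengenes and explained variance
#'
#' For each module, genes are standardized (z-score per gene) and the
#' eigengene is the first right-singular vector of the standardized
#' module submatrix: one value per sample, unit Euclidean norm.  Its
#' sign is oriented so the mean correlation with member genes is
#' non-negative; exact ties (e.g. a perfectly anticorrelated pair) are
#' broken so the first member gene (by row order) correlates positively.
#' `variance_explained` is the first squared singular value over the
#' total.
#'
#' @param mat genes x samples expression matrix.
#' @param labels module labels per gene (`"0"` ignored), named by gene.
#' @return list with `eigengenes` (modules x samples matrix, rows named
#'   `ME<id>`) and `variance_explained` (named vector).
#' @export
compute_eigengenes <- function(mat, labels) {
  .assert_matrix(mat, "mat")
  if (is.null(names(labels))) {
    if (length(labels) != nrow(mat))
      stop("'labels' must be named by gene or match nrow(mat)",
           call. = FALSE)
    names(labels) <- rownames(mat)
  }
  mods <- setdiff(unique(labels), "0")
  mods <- mods[order(suppressWarnings(as.numeric(mods)), mods)]
  if (!length(mods)) stop("no modules to summarize", call. = FALSE)
  eg <- matrix(NA_real_, length(mods), ncol(mat),
               dimnames = list(paste0("ME", mods), colnames(mat)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (j in seq_along(mods)) {
    genes <- names(labels)[labels == mods[j]]
    sub <- mat[genes, , drop = FALSE]
    if (nrow(sub) < 2)
      stop(sprintf("module %s has fewer than 2 genes", mods[j]),
           call. = FALSE)
    v <- .row_vars(sub)
    if (any(v == 0))
      stop(sprintf("module %s contains constant genes", mods[j]),
           call. = FALSE)
    z <- (sub - rowMeans(sub)) / sqrt(v)
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    cors <- as.numeric(stats::cor(t(sub), e))
    mc <- mean(cors)
    flip <- if (abs(mc) > 1e-10) sign(mc) else sign(cors[1])
    if (flip == 0) flip <- 1
    eg[j, ] <- e * flip
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, variance_explained = ve)
}

#' Merge highly correlated modules
#'
#' Iteratively merges the module pair with the largest absolute
#' eigengene correlation while it exceeds `r_merge`, recomputing
#' eigengenes after every merge (ties broken towards the lowest module
#' indices).  On return no eigengene pair correlates above `r_merge` in
#' absolute value.
#'
#' @param mat genes x samples matrix.
#' @param labels module labels per gene.
#' @param r_merge correlation threshold, default 0.75.
#' @return list with `labels` (merged), `eigengenes`,
#'   `variance_explained`.
#' @export
merge_modules <- function(mat, labels, r_merge = 0.75) {
  if (is.null(names(labels))) names(labels) <- rownames(mat)
  repeat {
    eg <- compute_eigengenes(mat, labels)
    E <- eg$eigengenes
    if (nrow(E) < 2) break
    C <- abs(stats::cor(t(E)))
    diag(C) <- 0
    if (max(C) <= r_merge) break
    idx <- which(C == max(C), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    ids <- sub("^ME", "", rownames(E)[sort(idx)])
    labels[labels == ids[2]] <- ids[1]
  }
  list(labels = labels, eigengenes = eg$eigengenes,
       variance_explained = eg$variance_explained)
}

#' Module membership (kME) and hub genes
#'
#' kME of a gene is the Pearson correlation between its profile and its
#' module's eigengene (signed, after the eigengene's orientation).  The
#' hub gene of a module maximizes kME; exact ties are broken towards the
#' lexicographically smaller gene id.
#'
#' @param mat genes x samples matrix.
#' @param labels module labels per gene.
#' @param eigengenes modules x samples eigengene matrix (rows `ME<id>`).
#' @return list with `kme` (data.frame: gene_id, module_id, kme) and
#'   `hubs` (data.frame: module_id, hub_gene, kme).
#' @export
hub_genes <- function(mat, labels, eigengenes) {
  if (is.null(names(labels))) names(labels) <- rownames(mat)
  mods <- sub("^ME", "", rownames(eigengenes))
  kme_list <- list()
  hubs <- NULL
  for (m in mods) {
    genes <- names(labels)[labels == m]
    e <- eigengenes[paste0("ME", m), ]
    km <- as.numeric(stats::cor(t(mat[genes, , drop = FALSE]), e))
    ord <- order(-km, genes)
    hubs <- rbind(hubs, data.frame(module_id = m,
                                   hub_gene = genes[ord[1]],
                                   kme = km[ord[1]],
                                   stringsAsFactors = FALSE))
    kme_list[[m]] <- data.frame(gene_id = genes, module_id = m, kme = km,
                                stringsAsFactors = FALSE)
  }
  list(kme = do.call(rbind, c(kme_list, make.row.names = FALSE)),
       hubs = hubs)
}

#' Detect co-expression modules in an expression matrix
#'
#' Full network stage: zero-variance filtering, correlation,
#' soft-threshold adjacency at `params$power`, TOM (or adjacency)
#' dissimilarity, average-linkage clustering, tree cut with minimum
#' module size, eigengene computation, merging of correlated modules at
#' `params$merge_cor_threshold`, relabelling by decreasing size, and
#' hub-gene/kME summaries.
#'
#' @param mat genes x samples expression matrix (log scale).
#' @param params a [network_params()].
#' @return object of class `module_set`: list with `labels`,
#'   `eigengenes`, `variance_explained`, `sizes`, `hubs`, `kme`,
#'   `dropped`, `params`.
#' @export
detect_modules <- function(mat, params = network_params()) {
  filt <- drop_zero_variance(mat)
  mat <- filt$mat
  cr <- correlation_matrix(mat, params$cor_method)
  adj <- soft_adjacency(cr, params$power)
  diss <- if (params$use_tom) 1 - topological_overlap(adj) else 1 - adj
  diag(diss) <- 0
  tree <- cluster_genes(diss)
  # Module *seeds* may be smaller than the final minimum size: a weak
  # module's branch core is grown afterwards by the membership
  # attachment step, and any module still below min_module_size at the
  # end is discarded.
  seed_params <- params
  seed_params$min_module_size <-
    max(5L, as.integer(ceiling(params$min_module_size / 2)))
  labels <- cut_tree_dynamic(tree, seed_params)
  labels <- .apply_ve_gate(mat, labels, params$ve_gate)
  labels <- .split_refine(mat, labels, diss, seed_params)

  # Alternate membership attachment with rescue clustering.  The
  # attachment step pulls peripheral genes (sufficient |kME|) into the
  # branch-core modules; the rescue step re-clusters what remains, so a
  # weaker module that fragmented at the global cut height chosen for
  # the strong modules can still surface.  Iterate until no further
  # gate-passing branch emerges.
  next_id <- suppressWarnings(
    max(0L, as.integer(labels), na.rm = TRUE)) + 1L
  for (outer in 1:3) {
    added <- FALSE
    repeat {
      if (any(labels != "0") && is.finite(params$pam_kme_threshold)) {
        eg0 <- compute_eigengenes(mat, labels)$eigengenes
        un <- names(labels)[labels == "0"]
        if (length(un)) {
          km <- abs(stats::cor(t(mat[un, , drop = FALSE]), t(eg0)))
          best <- max.col(km, ties.method = "first")
          ok <- km[cbind(seq_along(un), best)] >=
            params$pam_kme_threshold
          labels[un[ok]] <- sub("^ME", "", rownames(eg0))[best[ok]]
        }
      }
      un <- names(labels)[labels == "0"]
      if (length(un) < seed_params$min_module_size) break
      sub_tree <- cluster_genes(diss[un, un, drop = FALSE])
      sub_labels <- suppressWarnings(cut_tree_dynamic(sub_tree,
                                                      seed_params))
      sub_labels <- .apply_ve_gate(mat[un, , drop = FALSE], sub_labels,
                                   params$ve_gate)
      found <- setdiff(unique(sub_labels), "0")
      if (!length(found)) break
      for (f in found) {
        labels[names(sub_labels)[sub_labels == f]] <-
          as.character(next_id)
        next_id <- next_id + 1L
      }
      added <- TRUE
    }
    if (all(labels == "0")) break
    labels <- merge_modules(mat, labels,
                            params$merge_cor_threshold)$labels
    labels <- .kme_sweep(mat, labels, params$pam_kme_threshold)
    if (all(labels == "0")) break
    labels <- merge_modules(mat, labels,
                            params$merge_cor_threshold)$labels
    if (outer > 1 && !added) break
  }

  if (all(labels == "0")) {
    return(structure(list(labels = labels,
                          eigengenes = NULL, variance_explained = NULL,
                          sizes = integer(0), hubs = NULL, kme = NULL,
                          dropped = filt$dropped, params = params),
                     class = "module_set"))
  }

  # drop modules that never grew to the final minimum size
  sz0 <- table(labels[labels != "0"])
  for (m in names(sz0)[sz0 < params$min_module_size])
    labels[labels == m] <- "0"
  if (all(labels == "0")) {
    return(structure(list(labels = labels,
                          eigengenes = NULL, variance_explained = NULL,
                          sizes = integer(0), hubs = NULL, kme = NULL,
                          dropped = filt$dropped, params = params),
                     class = "module_set"))
  }

  # renumber by decreasing size (stable for ties)
  sz <- table(labels[labels != "0"])
  ord <- names(sz)[order(-sz, suppressWarnings(as.numeric(names(sz))))]
  relab <- stats::setNames(as.character(seq_along(ord)), ord)
  labels[labels != "0"] <- relab[labels[labels != "0"]]

  eg <- compute_eigengenes(mat, labels)
  hk <- hub_genes(mat, labels, eg$eigengenes)
  sizes <- table(labels[labels != "0"])
  sizes <- stats::setNames(as.integer(sizes), names(sizes))

  structure(list(labels = labels, eigengenes = eg$eigengenes,
                 variance_explained = eg$variance_explained,
                 sizes = sizes, hubs = hk$hubs, kme = hk$kme,
                 dropped = filt$dropped, params = params),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(x$sizes)
  cat(sprintf("module_set: %d module(s), %d gene(s) assigned, %d unassigned\n",
              n_mod, sum(x$labels != "0"), sum(x$labels == "0")))
  if (n_mod) {
    s <- x$sizes[order(-x$sizes)]
    cat("sizes:", paste(sprintf("%s=%d", names(s), s), collapse = ", "),
        "\n")
  }
  invisible(x)
}
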