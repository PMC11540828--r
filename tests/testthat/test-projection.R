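test_that("panel restriction reports coverage and evaluability", {
  module_genes <- list(
    M14 = sprintf("m14_%03d", 1:273),
    M39 = sprintf("m39_%03d", 1:83),
    Mx  = sprintf("mx_%03d", 1:30))
  panel <- c(sprintf("m14_%03d", 1:42), sprintf("m39_%03d", 1:2),
             sprintf("other_%d", 1:50))
  res <- restrict_to_panel(module_genes, panel)
  tab <- res$table
  expect_equal(tab$n_measured[tab$module_id == "M14"], 42)
  expect_equal(tab$n_measured[tab$module_id == "M39"], 2)
  expect_false(tab$evaluable[tab$module_id == "M39"])
  expect_false(tab$evaluable[tab$module_id == "Mx"])

  full <- restrict_to_panel(list(M = c("a", "b", "c")),
                            c("a", "b", "c", "d"))
  expect_equal(full$table$n_measured, 3)
  expect_error(restrict_to_panel(module_genes, character(0)),
               "non-empty")
})

test_that("DEG fractions use a strict more-than threshold", {
  genes <- sprintf("g%d", 1:10)
  tab <- data.frame(gene_id = genes,
                    is_deg = c(rep(TRUE, 3), rep(FALSE, 7)))
  fr <- deg_fraction(genes, tab)
  expect_equal(fr$fraction, 0.3)
  expect_true(fr$activated)

  tab2 <- tab; tab2$is_deg <- c(rep(TRUE, 2), rep(FALSE, 8))
  fr2 <- deg_fraction(genes, tab2)
  expect_equal(fr2$fraction, 0.2)
  expect_false(fr2$activated)  # exactly 20% is not "more than 20%"

  small <- deg_fraction(genes[1:2], tab)
  expect_false(small$evaluable)

  set.seed(1)
  for (i in 1:20) {
    flags <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    t3 <- data.frame(gene_id = genes, is_deg = flags)
    expect_equal(deg_fraction(genes, t3)$n_deg, sum(flags))
  }
})

test_that("module scores average absolute fold changes with optional kME weights", {
  genes <- c("a", "b", "c")
  tab <- data.frame(gene_id = genes, log2fc = c(1, -1, 2))
  expect_equal(module_score(genes, tab)$score, 4 / 3)
  expect_equal(module_score(genes,
                            data.frame(gene_id = genes,
                                       log2fc = c(0, 0, 0)))$score, 0)

  kme <- setNames(c(0.5, 0.5, 0.5), genes)
  expect_equal(module_score(genes, tab, "kme", kme)$score, 4 / 3)
  kme2 <- setNames(c(1, 0.1, 0.1), genes)
  expect_gt(abs(module_score(genes, tab, "kme", kme2)$score - 4 / 3),
            0.01)

  # missing genes excluded and counted
  res <- module_score(c(genes, "zz"), tab)
  expect_equal(res$n_missing, 1)
  expect_equal(res$score, 4 / 3)
  none <- module_score("zz", tab)
  expect_false(none$evaluable)

  # plain score scales exactly with |log2FC|
  tab3 <- tab; tab3$log2fc <- tab$log2fc * 2.5
  expect_equal(module_score(genes, tab3)$score,
               2.5 * module_score(genes, tab)$score)
})

test_that("concentration trends match closed-form least squares", {
  tr <- concentration_trend(c(0.1, 0.2, 0.3, 0.4), 10^(0:3))
  expect_equal(tr$slope, 0.1, tolerance = 1e-12)

  flat <- concentration_trend(rep(0.5, 4), 10^(0:3))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_false(isTRUE(flat$dose_responsive))

  set.seed(2)
  x <- log10(c(0.1, 0.3, 1, 3, 10))
  y <- 0.4 * x + rnorm(5, sd = 0.1)
  tr2 <- concentration_trend(y, c(0.1, 0.3, 1, 3, 10))
  Sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / Sxx
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / 3 / Sxx)
  expect_equal(tr2$slope, slope, tolerance = 1e-10)
  expect_equal(tr2$se, se, tolerance = 1e-10)
  expect_equal(tr2$p, 2 * pt(-abs(slope / se), 3), tolerance = 1e-10)
  expect_equal(tr2$ci_lower, slope - qt(0.975, 3) * se,
               tolerance = 1e-10)

  two <- concentration_trend(c(0.2, 0.6), c(1, 10))
  expect_true(is.na(two$p))
  expect_equal(two$slope, 0.4, tolerance = 1e-12)
  expect_error(concentration_trend(c(1, 2), c(-1, 2)), "positive")
})

test_that("recurrent DEGs require at least two concentrations per compound", {
  genes <- sprintf("g%d", 1:4)
  mk <- function(flags) data.frame(gene_id = genes, is_deg = flags)
  tabs <- list(mk(c(TRUE, TRUE, FALSE, FALSE)),
               mk(c(TRUE, FALSE, FALSE, FALSE)),
               mk(c(FALSE, FALSE, TRUE, FALSE)),
               mk(c(FALSE, FALSE, FALSE, FALSE)),
               mk(c(FALSE, FALSE, TRUE, FALSE)))
  rec <- recurrent_degs(genes, tabs)
  expect_equal(rec, c("g1", "g3"))  # g2 hit once only, excluded
  expect_error(recurrent_degs(genes, tabs[1]), ">= 2")
})

test_that("projection drives activation, trends and cross-compound recurrence", {
  module_genes <- list(A = sprintf("a%d", 1:10),
                       B = sprintf("b%d", 1:10))
  panel <- c(module_genes$A[1:5], module_genes$B[1:5])
  concs <- c(1, 10)
  manifest <- data.frame(
    condition_id = c("c1_1", "c1_2", "c2_1", "c2_2"),
    compound = c("c1", "c1", "c2", "c2"),
    concentration = rep(concs, 2))
  mk <- function(lfc, deg) data.frame(gene_id = panel, log2fc = lfc,
                                      is_deg = deg)
  up <- c(rep(2, 5), rep(0.1, 5))
  deg_a <- c(rep(TRUE, 5), rep(FALSE, 5))
  tabs <- list(c1_1 = mk(up * 0.5, deg_a), c1_2 = mk(up, deg_a),
               c2_1 = mk(up * 0.4, deg_a), c2_2 = mk(up * 0.9, deg_a))
  proj <- project_modules(module_genes, panel, tabs, manifest)

  act <- proj$activation
  expect_equal(nrow(act), 2 * 4)
  expect_true(all(act$activated[act$module_id == "A"]))
  expect_false(any(act$activated[act$module_id == "B"]))
  expect_equal(act$score[act$module_id == "A" &
                           act$condition_id == "c1_2"], 2)

  # order invariance of genes and conditions
  proj2 <- project_modules(lapply(module_genes, rev), rev(panel),
                           tabs[c(3, 1, 4, 2)],
                           manifest[c(4, 2, 3, 1), ])
  a1 <- act[order(act$module_id, act$condition_id), ]
  a2 <- proj2$activation[order(proj2$activation$module_id,
                               proj2$activation$condition_id), ]
  expect_equal(a1$fraction, a2$fraction)
  expect_equal(a1$score, a2$score)

  # recurrent DEGs flagged across compounds
  rec <- proj$recurrent
  expect_true(all(sort(unique(rec$gene_id)) == sort(module_genes$A[1:5])))
  expect_true(all(rec$cross_compound))

  expect_error(project_modules(module_genes, panel, tabs[1:3],
                               manifest),
               "missing DEG table")
})
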