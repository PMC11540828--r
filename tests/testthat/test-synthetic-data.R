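test_that("phase trajectories peak in their phase and hold baseline elsewhere", {
  expect_equal(phase_trajectory("inflammatory", 1), 1.0)
  expect_equal(phase_trajectory("inflammatory", c(1, 2, 7, 21)),
               c(1, 1, 0.1, 0.1))
  expect_equal(phase_trajectory("late", 7), 0.1)
  expect_equal(phase_trajectory("late", c(21, 28, 35)), c(1, 1, 1))
  expect_equal(phase_trajectory("acute", c(7, 14)), c(1, 1))
  expect_equal(phase_trajectory("general", c(1, 14, 35)), c(1, 1, 1))
  expect_equal(phase_trajectory("null", c(1, 7, 35)), c(0, 0, 0))
  expect_equal(phase_trajectory("late", 2, baseline = 0.25), 0.25)
  expect_error(phase_trajectory("fibrotic", 1), "arg")
  expect_error(phase_trajectory("late", -1), "positive")
})

test_that("simulation configs validate module plans and sizes", {
  expect_error(module_plan("M1", 20, "inflammatory"), "size")
  expect_error(module_plan("M1", 40, "null", amplitude = 1),
               "amplitude 0")
  expect_error(
    simulation_config(n_genes = 100,
                      module_plans = list(module_plan("M1", 200,
                                                      "acute"))),
    "exceed")
  expect_error(simulation_config(n_per_group = 1), "n_per_group")
  cfg <- simulation_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(sum(vapply(cfg$module_plans, `[[`, 1L, "size")), 1016L)
})

test_that("in vivo simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_genes = 1100, n_per_group = 2, seed = 7)
  a <- simulate_invivo(cfg)
  b <- simulate_invivo(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$expr), c(1100, 2 * 2 * 7))
  expect_identical(sort(unique(a$design$phase)),
                   c("acute", "control", "inflammatory", "late"))
  # every planted gene belongs to exactly one module
  expect_equal(sum(a$truth$labels != "0"), 1016)
})

test_that("zero-amplitude modules are indistinguishable from background", {
  plans <- list(module_plan("M1", 60, "inflammatory", amplitude = 0))
  cfg <- simulation_config(n_genes = 260, module_plans = plans,
                           n_per_group = 4, seed = 11)
  sim <- simulate_invivo(cfg)
  inside <- sim$expr[sim$truth$labels == "M1", ]
  outside <- sim$expr[sim$truth$labels == "0", ][1:60, ]
  cor_in <- cor(t(inside)); cor_out <- cor(t(outside))
  pairs_in <- cor_in[upper.tri(cor_in)]
  pairs_out <- cor_out[upper.tri(cor_out)]
  expect_gt(t.test(pairs_in, pairs_out)$p.value, 0.01)
})

test_that("planted modules exceed background correlation, against a brute-force oracle", {
  plans <- list(module_plan("M1", 50, "acute", amplitude = 1.5,
                            loading_range = c(0.4, 0.9)))
  cfg <- simulation_config(n_genes = 300, module_plans = plans,
                           n_per_group = 4, noise_sd = 1, seed = 3)
  sim <- simulate_invivo(cfg)
  treated <- sim$design$sample_id[sim$design$group == "treated"]
  x <- sim$expr[, treated]
  # brute-force Pearson correlation for a handful of pairs
  brute_cor <- function(u, v) {
    um <- mean(u); vm <- mean(v)
    sum((u - um) * (v - vm)) /
      sqrt(sum((u - um)^2) * sum((v - vm)^2))
  }
  cc <- cor(t(x))
  for (pair in list(c(1, 2), c(3, 40), c(10, 50))) {
    expect_equal(brute_cor(x[pair[1], ], x[pair[2], ]),
                 cc[pair[1], pair[2]], tolerance = 1e-12)
  }
  in_idx <- which(sim$truth$labels == "M1")
  out_idx <- which(sim$truth$labels == "0")[1:50]
  mean_abs <- function(idx) {
    m <- abs(cc[idx, idx]); mean(m[upper.tri(m)])
  }
  expect_gt(mean_abs(in_idx), mean_abs(out_idx))
})

test_that("loading sign flips leave correlation magnitudes unchanged", {
  cfg <- simulation_config(n_genes = 1100, n_per_group = 2, seed = 5)
  sim <- simulate_invivo(cfg)
  x <- sim$expr[1:20, ]
  flipped <- x * c(-1, 1)[1 + seq_len(20) %% 2]
  expect_equal(abs(cor(t(x))), abs(cor(t(flipped))), tolerance = 1e-12)
})

test_that("in vitro series plants class-consistent, monotone fold changes", {
  truth <- make_truth_modules()
  panel <- default_panel(truth, seed = 1)
  vit <- simulate_invitro(truth, panel, seed = 1)
  expect_equal(nrow(vit$manifest), 5 * 5)

  inert <- vit$conditions[["solvent_c5"]]
  expect_true(all(inert$planted_lfc == 0))

  fib_ids <- sprintf("diketone_A_c%d", 1:5)
  lfc <- sapply(fib_ids, function(id)
    abs(vit$conditions[[id]]$planted_lfc))
  expect_true(all(diff(t(lfc)[, colSums(lfc) > 0]) >= 0))

  # per-module mean planted |log2FC| at each level matches the
  # generative dose-effect formula evaluated by hand
  top <- vit$conditions[["diketone_A_c5"]]
  hit <- abs(top$planted_lfc) > 0
  expect_equal(unname(abs(top$planted_lfc[hit])),
               rep(2.0, sum(hit)))
  mid <- vit$conditions[["diketone_A_c2"]]
  expect_equal(unname(abs(mid$planted_lfc[abs(mid$planted_lfc) > 0])),
               rep(2.0 * 2 / 5, sum(hit)))

  # inflammation-only compound shifts only inflammatory-profile modules
  infl <- vit$conditions[["misfolder_c5"]]
  shifted <- names(infl$planted_lfc)[infl$planted_lfc != 0]
  mods <- unique(truth$labels[shifted])
  expect_true(all(truth$profiles[mods] == "inflammatory"))

  expect_error(simulate_invitro(truth, character(0)), "non-empty")
  expect_identical(simulate_invitro(truth, panel, seed = 2),
                   simulate_invitro(truth, panel, seed = 2))
})

test_that("count mode produces reproducible negative-binomial counts", {
  cfg <- simulation_config(n_genes = 1100, n_per_group = 2,
                           count_mode = TRUE, seed = 9)
  sim <- simulate_invivo(cfg)
  expect_true(all(sim$expr >= 0))
  expect_true(all(sim$expr == round(sim$expr)))
  expect_identical(sim$expr, simulate_invivo(cfg)$expr)
})
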