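#!/usr/bin/env Rscript
# Stage 3: weighted co-expression network and module detection.
# Soft-threshold adjacency at power 4, TOM dissimilarity,
# average-linkage clustering with adaptive tree cut (minimum module
# size 30), eigengene merging at r > 0.75.  Also prints the
# scale-free-fit scan that motivates the soft-threshold choice.

library(fibromod)
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1L

expr <- read_expression_tsv("results/run/expression.tsv")
scan <- pick_soft_threshold(correlation_matrix(drop_zero_variance(expr)$mat),
                            powers = c(1, 2, 4, 6, 8))
cat("soft-threshold scan (signed scale-free R^2, mean connectivity):\n")
print(scan, digits = 3)

run_pipeline(list(seed = seed), "results/run", stages = "network")
mods <- read_module_tsv("results/run/modules.tsv")
sz <- table(mods$labels[mods$labels != "0"])
cat(sprintf("detected %d modules (sizes %s); %d genes unassigned\n",
            length(sz), paste(sort(as.integer(sz), decreasing = TRUE),
                              collapse = ", "),
            sum(mods$labels == "0")))
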