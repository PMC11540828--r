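#!/usr/bin/env Rscript
# Stage 1: generate the synthetic bleomycin-style time course.
# A 2,000-gene matrix over 7 sampling days (8 treated + 8 control mice
# per day) with eight planted phase-specific co-expression modules,
# written as TSVs under results/run/ together with the truth labels.

library(fibromod)
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1L

man <- run_pipeline(list(seed = seed), "results/run",
                    stages = "simulate")
design <- read.delim("results/run/design.tsv")
truth <- read.delim("results/run/truth.tsv")
cat(sprintf("simulated %d genes x %d samples (%d treated, %d control)\n",
            man$rows$simulate, nrow(design),
            sum(design$group == "treated"),
            sum(design$group == "control")))
print(table(module = truth$module_id))
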