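#!/usr/bin/env Rscript
# Stage 6: project the frozen modules onto a synthetic targeted-panel
# concentration-response experiment (five compounds: three
# fibrosis-inducing, one inflammation-only, one inert; five
# concentrations; 3 vs 3 replicates).  Reports per-module DEG-fraction
# activation calls and module-score concentration trends.

library(fibromod)
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1L

run_pipeline(list(seed = seed), "results/run", stages = "project")
act <- read.delim("results/run/projection_activation.tsv")
tr <- read.delim("results/run/projection_trend.tsv")

cat("activated concentration levels per module x compound:\n")
print(with(act[act$evaluable, ],
           tapply(activated, list(module_id, compound), sum)))
cat("\ndose-responsive module scores (slope > 0, p < 0.05):\n")
print(with(tr, tapply(dose_responsive, list(module_id, compound),
                      identity)))
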