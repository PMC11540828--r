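#!/usr/bin/env Rscript
# Stage 2: per-day differential expression (treated day vs pooled
# controls; Welch t on the expression matrix, BH adjustment, DEG at
# padj < 0.05 and |log2FC| >= 1).  Prints the per-day up/down counts --
# the time-dependent DEG pattern across disease phases.

library(fibromod)
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1L

run_pipeline(list(seed = seed), "results/run", stages = "deg")
files <- sort(list.files("results/run/deg", full.names = TRUE))
for (f in files) {
  tab <- read_deg_table(f)
  cat(sprintf("%s: %4d up, %4d down\n",
              sub("deg_|\\.tsv", "", basename(f)),
              sum(tab$is_deg & tab$log2fc > 0),
              sum(tab$is_deg & tab$log2fc < 0)))
}
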