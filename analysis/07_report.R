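#!/usr/bin/env Rscript
# Stage 7: human-readable summary of the full run.

library(fibromod)
lines <- write_report("results/run", "results/report.txt")
cat(readLines("results/report.txt"), sep = "\n")
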