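#!/usr/bin/env Rscript
# Stage 5: annotation of the selected modules.  Maps module genes to
# the target (human-like) namespace through the bundled synthetic
# ortholog table, counts overlaps with a synthetic fibrosis-biomarker
# list, and runs gene-set over-representation (one-sided Fisher/
# hypergeometric, BH within module) against a small synthetic GO-style
# collection.  All reference files are synthetic stand-ins bundled
# under inst/extdata/.

library(fibromod)

mods <- read_module_tsv("results/run/modules.tsv")
rep <- read.delim("results/run/phase_activity.tsv",
                  colClasses = c(module_id = "character"))
selected <- rep$module_id[rep$selected]
gene_lists <- module_gene_lists(mods$labels)[selected]

map <- read_ortholog_map(system.file("extdata",
                                     "synthetic_ortholog_map.tsv",
                                     package = "fibromod"))
mapped <- map_orthologs(gene_lists, map)
cat("ortholog mapping per selected module:\n")
print(mapped$report, row.names = FALSE)

bio <- readLines(system.file("extdata",
                             "synthetic_fibrosis_biomarkers.txt",
                             package = "fibromod"))
cat("\nbiomarker overlap per module:\n")
for (m in names(mapped$mapped)) {
  ov <- biomarker_overlap(mapped$mapped[[m]], bio)
  cat(sprintf("module %s: %d biomarker gene(s)\n", m, ov$n))
}

sets <- read_gmt(system.file("extdata", "synthetic_go_sets.gmt",
                             package = "fibromod"))
universe <- unique(unlist(map_orthologs(
  module_gene_lists(mods$labels), map)$mapped))
enr_all <- NULL
for (m in names(mapped$mapped)) {
  enr <- fisher_enrichment(mapped$mapped[[m]], sets, universe)
  enr$module_id <- m
  enr_all <- rbind(enr_all, enr)
}
write.table(enr_all, "results/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d enrichment rows written to results/enrichment.tsv; %d at padj < 0.05\n",
            nrow(enr_all), sum(enr_all$padj < 0.05)))
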