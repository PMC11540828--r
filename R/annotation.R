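#' Read a GMT gene-set file
#'
#' Standard tab-separated gene-set format: one set per line, fields are
#' set name, description, then gene ids.
#'
#' @param path GMT file path.
#' @return named list of gene-id vectors; descriptions in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("%s: malformed GMT line(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2), names(sets))
  sets
}

#' Read a two-column ortholog map
#'
#' @param path TSV with a header and two columns: source gene id, target
#'   gene id.  One-to-many mappings occupy several rows.
#' @return data.frame with columns `source`, `target`; the mapping
#'   direction is recorded in the `"direction"` attribute.
#' @export
read_ortholog_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2)
    stop(sprintf("%s: ortholog map needs two columns", path),
         call. = FALSE)
  out <- data.frame(source = tab[[1]], target = tab[[2]],
                    stringsAsFactors = FALSE)
  bad <- which(!nzchar(out$source) | !nzchar(out$target) |
                 is.na(out$source) | is.na(out$target))
  if (length(bad))
    stop(sprintf("%s: empty identifier(s) at data line(s) %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  attr(out, "direction") <- paste(names(tab)[1], "->", names(tab)[2])
  out
}

#' Map module genes through an ortholog table
#'
#' Translates each module's gene list to the target namespace.  Genes
#' without any target are dropped and counted; one-to-many mappings
#' expand to all targets (deduplicated per module).
#'
#' @param module_genes named list of gene-id vectors per module.
#' @param map data.frame with columns `source`, `target` (see
#'   [read_ortholog_map()]).
#' @return list with `mapped` (named list of target gene ids per module)
#'   and `report` (data.frame: module_id, n_input, n_mapped, n_dropped,
#'   n_targets).
#' @export
map_orthologs <- function(module_genes, map) {
  if (!all(c("source", "target") %in% names(map)))
    stop("'map' needs columns source and target", call. = FALSE)
  mapped <- list()
  report <- NULL
  for (m in names(module_genes)) {
    genes <- unique(module_genes[[m]])
    hit <- genes %in% map$source
    targets <- sort(unique(map$target[map$source %in% genes]))
    mapped[[m]] <- targets
    report <- rbind(report,
                    data.frame(module_id = m,
                               n_input = length(genes),
                               n_mapped = sum(hit),
                               n_dropped = sum(!hit),
                               n_targets = length(targets),
                               stringsAsFactors = FALSE))
  }
  list(mapped = mapped, report = report)
}

#' Overlap between module genes and a biomarker list
#'
#' @param module_genes character vector of gene ids.
#' @param biomarkers non-empty character vector of biomarker gene ids.
#' @return list with `n` (overlap count) and `genes` (sorted overlap).
#' @export
biomarker_overlap <- function(module_genes, biomarkers) {
  if (!length(biomarkers))
    stop("'biomarkers' must be non-empty", call. = FALSE)
  ov <- sort(intersect(unique(module_genes), unique(biomarkers)))
  list(n = length(ov), genes = ov)
}

#' Gene-set over-representation by Fisher's exact test
#'
#' One-sided (over-representation) hypergeometric p-value for each gene
#' set against a module, from the 2x2 table of in-module versus in-set
#' membership over a fixed universe, with Benjamini-Hochberg adjustment
#' across sets.  Gene sets are intersected with the universe; the module
#' must be a subset of the universe.
#'
#' @param module_genes gene ids of one module (subset of `universe`).
#' @param gene_sets named list of gene-id vectors (e.g. [read_gmt()]).
#' @param universe background gene ids (non-empty).
#' @return data.frame sorted by padj then set name: gene_set, overlap,
#'   module_size, set_size, universe_size, p, padj.
#' @export
fisher_enrichment <- function(module_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("'universe' must be non-empty",
                              call. = FALSE)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    stop("'module_genes' must be a subset of 'universe'", call. = FALSE)
  N <- length(universe)
  m <- length(module_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s_genes <- intersect(unique(gene_sets[[nm]]), universe)
    s <- length(s_genes)
    k <- length(intersect(module_genes, s_genes))
    # P(X >= k) for X ~ Hypergeom(white = s, black = N - s, drawn = m)
    p <- stats::phyper(k - 1, s, N - s, m, lower.tail = FALSE)
    data.frame(gene_set = nm, overlap = k, module_size = m,
               set_size = s, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out <- out[order(out$padj, out$gene_set), ]
  rownames(out) <- NULL
  out
}

#' Genes of each module as a named list
#'
#' Convenience accessor turning a label vector (or `module_set`) into a
#' module-to-genes list, excluding the unassigned label `"0"`.
#'
#' @param x a `module_set` or a named gene-to-module label vector.
#' @return named list of gene-id vectors.
#' @export
module_gene_lists <- function(x) {
  labels <- if (inherits(x, "module_set")) x$labels else x
  mods <- setdiff(unique(labels), "0")
  mods <- mods[order(suppressWarnings(as.numeric(mods)), mods)]
  stats::setNames(lapply(mods, function(m) names(labels)[labels == m]),
                  mods)
}
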