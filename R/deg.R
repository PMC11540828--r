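#' Counts-per-million log2 normalization
#'
#' Scales every sample (column) to counts per million and applies
#' `log2(x + 1)`.  Library-depth differences between samples cancel
#' exactly, so multiplying any column by a constant leaves the output
#' unchanged.
#'
#' @param mat non-negative genes x samples matrix.
#' @return matrix of the same shape, log2 CPM values.
#' @export
cpm_log_normalize <- function(mat) {
  .assert_matrix(mat, "mat")
  if (any(mat < 0)) stop("'mat' must be non-negative", call. = FALSE)
  libs <- colSums(mat)
  if (any(libs == 0)) {
    bad <- colnames(mat)[libs == 0]
    if (is.null(bad)) bad <- which(libs == 0)
    stop(sprintf("all-zero sample column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  log2(sweep(mat, 2, libs, "/") * 1e6 + 1)
}

#' Define a treated-versus-control contrast
#'
#' @param treated,control disjoint non-empty sample id vectors, each with
#'   at least two samples so a two-sample test is defined.
#' @param label human-readable contrast label.
#' @return object of class `contrast`.
#' @export
contrast <- function(treated, control, label = "contrast") {
  if (length(treated) < 2 || length(control) < 2)
    stop("each contrast side needs >= 2 samples", call. = FALSE)
  if (length(intersect(treated, control)))
    stop("'treated' and 'control' must be disjoint", call. = FALSE)
  structure(list(treated = as.character(treated),
                 control = as.character(control),
                 label = as.character(label)), class = "contrast")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values.  Thin,
#' validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]; `NaN`/`NA`
#'   entries are rejected.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)))
    stop("'pvalues' must be finite numbers in [0, 1]", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1))
    stop("'pvalues' must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-gene differential expression (Welch t-test on log scale)
#'
#' Computes, for every gene, the log2 fold change as the difference of
#' group means on the (already log2-scale) matrix and a Welch two-sample
#' t-test p-value with Welch-Satterthwaite degrees of freedom, followed
#' by Benjamini-Hochberg adjustment.  When both groups have zero
#' variance and equal means the p-value is 1 by convention; with zero
#' variance and unequal means it is 0.
#'
#' @param mat normalized (log2-scale) genes x samples matrix with sample
#'   ids as column names.
#' @param ct a [contrast()] whose sample ids occur in `mat`.
#' @return `data.frame` with columns gene_id, log2fc, pvalue, padj.
#' @export
differential_expression <- function(mat, ct) {
  .assert_matrix(mat, "mat")
  if (!inherits(ct, "contrast"))
    stop("'ct' must be a contrast()", call. = FALSE)
  miss <- setdiff(c(ct$treated, ct$control), colnames(mat))
  if (length(miss))
    stop(sprintf("samples not in matrix: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  x <- mat[, ct$treated, drop = FALSE]
  y <- mat[, ct$control, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- .row_vars(x); v2 <- .row_vars(y)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tt <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0
  p[degenerate & lfc == 0] <- 1
  p[degenerate & lfc != 0] <- 0
  gene_id <- rownames(mat)
  if (is.null(gene_id)) gene_id <- sprintf("gene%d", seq_len(nrow(mat)))
  data.frame(gene_id = gene_id, log2fc = lfc, pvalue = p,
             padj = bh_adjust(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Flags genes with adjusted p below `padj_cut` (strict) and absolute
#' log2 fold change of at least `lfc_cut` (inclusive).
#'
#' @param table data.frame with columns `padj` and `log2fc` (e.g. from
#'   [differential_expression()]).
#' @param padj_cut adjusted-p threshold, default 0.05 (strict `<`).
#' @param lfc_cut absolute log2FC threshold, default 1 (inclusive `>=`).
#' @return list with `table` (input plus logical `is_deg`), `n_up` and
#'   `n_down` counts.
#' @export
call_degs <- function(table, padj_cut = 0.05, lfc_cut = 1.0) {
  if (!all(c("padj", "log2fc") %in% names(table)))
    stop("'table' needs columns 'padj' and 'log2fc'", call. = FALSE)
  table$is_deg <- table$padj < padj_cut & abs(table$log2fc) >= lfc_cut
  list(table = table,
       n_up = sum(table$is_deg & table$log2fc > 0),
       n_down = sum(table$is_deg & table$log2fc < 0))
}

#' Read a per-condition DEG table
#'
#' Accepts externally produced tab-separated DEG tables with columns
#' gene_id, log2fc, pvalue, padj and optionally is_deg; a missing
#' `is_deg` column is recomputed from the thresholds.
#'
#' @param path TSV file path.
#' @param padj_cut,lfc_cut thresholds used when `is_deg` is absent.
#' @return data.frame with the five DEG columns.
#' @export
read_deg_table <- function(path, padj_cut = 0.05, lfc_cut = 1.0) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "padj")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!"is_deg" %in% names(tab))
    tab <- call_degs(tab, padj_cut, lfc_cut)$table
  tab$is_deg <- as.logical(tab$is_deg)
  tab
}

#' Write a DEG table as TSV
#'
#' @param table DEG data.frame.
#' @param path output file path.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
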