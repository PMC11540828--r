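#' Sample-to-phase map
#'
#' Derives the phase class of every sample from the design table:
#' control samples (all timepoints pooled) form the `"control"` class;
#' treated samples map to `"inflammatory"` (days 1-2), `"acute"`
#' (days 7-14) or `"late"` (day 21 onwards).
#'
#' @param design data.frame with columns sample_id, day, group.
#' @return named character vector sample_id -> phase.
#' @export
phase_map <- function(design) {
  need <- c("sample_id", "day", "group")
  if (!all(need %in% names(design)))
    stop("'design' needs columns sample_id, day, group", call. = FALSE)
  ph <- ifelse(design$group == "control", "control",
               day_to_phase(design$day))
  if (!any(ph == "control"))
    stop("design contains no control samples", call. = FALSE)
  stats::setNames(ph, design$sample_id)
}

#' Per-phase eigengene activity scores
#'
#' The activity of a module in a phase is the mean of the *absolute*
#' eigengene entries over that phase's samples, so positively and
#' negatively deflected samples cannot cancel.
#'
#' @param eigengenes modules x samples matrix (rows `ME<id>`), columns
#'   named by sample id.
#' @param phases named phase vector from [phase_map()]; must cover all
#'   eigengene columns and every phase class present must be non-empty.
#' @return modules x phases matrix of non-negative EG scores.
#' @export
phase_scores <- function(eigengenes, phases) {
  .assert_matrix(eigengenes, "eigengenes")
  if (is.null(colnames(eigengenes)) ||
      !all(colnames(eigengenes) %in% names(phases)))
    stop("eigengene samples must all appear in the phase map",
         call. = FALSE)
  ph <- phases[colnames(eigengenes)]
  lev <- intersect(c("inflammatory", "acute", "late", "control"),
                   unique(ph))
  if (!length(lev)) stop("no phase classes present", call. = FALSE)
  out <- sapply(lev, function(p) {
    cols <- ph == p
    if (!any(cols))
      stop(sprintf("phase class '%s' is empty", p), call. = FALSE)
    rowMeans(abs(eigengenes[, cols, drop = FALSE]))
  })
  out <- matrix(out, nrow = nrow(eigengenes),
                dimnames = list(rownames(eigengenes), lev))
  out
}

#' Differential activity (DA)
#'
#' Ratio of a module's phase activity to its control activity:
#' `DA(m, P) = EG_score(m, P) / EG_score(m, control)`.  Control samples
#' achieve non-zero activity, so DA near 1 means "no different from
#' control".  A control score below `eps` is guarded (divided by `eps`)
#' and flagged unstable with a warning.
#'
#' @param scores modules x phases EG-score matrix from [phase_scores()];
#'   must contain a `"control"` column.
#' @param eps guard for the control denominator, default 1e-8.
#' @return list with `da` (modules x non-control phases matrix) and
#'   `unstable` (logical per module).
#' @export
differential_activity <- function(scores, eps = 1e-8) {
  .assert_matrix(scores, "scores")
  if (!"control" %in% colnames(scores))
    stop("'scores' must contain a control column", call. = FALSE)
  ctrl <- scores[, "control"]
  unstable <- ctrl < eps
  if (any(unstable))
    warning(sprintf("control activity below eps for module(s): %s; DA unstable",
                    paste(rownames(scores)[unstable], collapse = ", ")))
  denom <- pmax(ctrl, eps)
  ph <- setdiff(colnames(scores), "control")
  da <- scores[, ph, drop = FALSE] / denom
  list(da = da, unstable = stats::setNames(unstable, rownames(scores)))
}

#' Select phase-active modules by differential activity
#'
#' A module is selected when its DA reaches `threshold` (inclusive, the
#' convention of the printed module table where a DA of exactly 2.50 is
#' counted) in at least one phase, and is assigned to every phase whose
#' DA reaches the threshold.
#'
#' @param da modules x phases DA matrix (rows `ME<id>` or module ids).
#' @param threshold selection threshold, default 2.5.
#' @return data.frame with module_id, selected, assigned_phases
#'   (comma-separated), max_phase, and one `DA_<phase>` column per phase.
#' @export
select_modules <- function(da, threshold = 2.5) {
  .assert_matrix(da, "da")
  .assert_scalar_number(threshold, "threshold", lower = 0)
  phases <- colnames(da)
  hits <- da >= threshold
  assigned <- apply(hits, 1, function(h)
    paste(phases[h], collapse = ","))
  out <- data.frame(module_id = sub("^ME", "", rownames(da)),
                    selected = rowSums(hits) > 0,
                    assigned_phases = assigned,
                    max_phase = phases[max.col(da, ties.method = "first")],
                    stringsAsFactors = FALSE)
  for (p in phases) out[[paste0("DA_", p)]] <- da[, p]
  rownames(out) <- NULL
  out
}

#' Phase-activity report for a module set
#'
#' Drives the phase-activity computation end to end: EG scores per
#' phase, DA per non-control phase, selection and phase assignment, and
#' hub genes, one row per module (label `"0"` excluded), ordered by
#' module id.
#'
#' @param module_set a `module_set` from [detect_modules()].
#' @param phases named phase vector from [phase_map()].
#' @param threshold DA selection threshold, default 2.5.
#' @return data.frame with module_id, size, hub_gene, per-phase
#'   `EG_<phase>` and `DA_<phase>` columns, selected, assigned_phases,
#'   max_phase, unstable.
#' @export
phase_activity_report <- function(module_set, phases, threshold = 2.5) {
  if (is.null(module_set$eigengenes))
    stop("module set has no modules to report", call. = FALSE)
  sc <- phase_scores(module_set$eigengenes, phases)
  act <- differential_activity(sc)
  sel <- select_modules(act$da, threshold)
  ids <- sel$module_id
  out <- data.frame(module_id = ids,
                    size = as.integer(module_set$sizes[ids]),
                    hub_gene = module_set$hubs$hub_gene[
                      match(ids, module_set$hubs$module_id)],
                    stringsAsFactors = FALSE)
  for (p in colnames(sc)) out[[paste0("EG_", p)]] <- sc[, p]
  out <- cbind(out, sel[, grep("^DA_", names(sel)), drop = FALSE])
  out$selected <- sel$selected
  out$assigned_phases <- sel$assigned_phases
  out$max_phase <- sel$max_phase
  out$unstable <- act$unstable[paste0("ME", ids)]
  ord <- order(suppressWarnings(as.numeric(out$module_id)),
               out$module_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
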