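#' Projection parameters
#'
#' @param activation_fraction_threshold DEG fraction above which (strict
#'   `>`) a module counts as activated in a condition; default 0.20.
#' @param min_measured_genes minimum panel coverage for a module to be
#'   evaluable; default 3 (guards against one-gene "modules").
#' @param trend_alpha significance level of the concentration-trend
#'   call; default 0.05.
#' @param score_weighting `"plain"` (unweighted mean of |log2FC|,
#'   default) or `"kme"` (kME-weighted mean).
#' @return object of class `projection_params`.
#' @export
projection_params <- function(activation_fraction_threshold = 0.20,
                              min_measured_genes = 3,
                              trend_alpha = 0.05,
                              score_weighting = c("plain", "kme")) {
  .assert_scalar_number(activation_fraction_threshold,
                        "activation_fraction_threshold",
                        lower = 1e-8, upper = 1 - 1e-8)
  .assert_scalar_number(min_measured_genes, "min_measured_genes",
                        lower = 1, integer = TRUE)
  .assert_scalar_number(trend_alpha, "trend_alpha", lower = 1e-8,
                        upper = 1 - 1e-8)
  structure(list(activation_fraction_threshold =
                   activation_fraction_threshold,
                 min_measured_genes = as.integer(min_measured_genes),
                 trend_alpha = trend_alpha,
                 score_weighting = match.arg(score_weighting)),
            class = "projection_params")
}

#' Restrict modules to a measured panel
#'
#' Intersects each module's gene list with the measured panel and flags
#' modules whose coverage falls below `min_measured_genes` as not
#' evaluable.
#'
#' @param module_genes named list of gene ids per module (see
#'   [module_gene_lists()]).
#' @param panel non-empty character vector of measured gene ids.
#' @param params a [projection_params()].
#' @return list with `measured` (named list of measured gene ids per
#'   module) and `table` (data.frame: module_id, n_genes, n_measured,
#'   evaluable).
#' @export
restrict_to_panel <- function(module_genes, panel,
                              params = projection_params()) {
  if (!length(panel)) stop("'panel' must be non-empty", call. = FALSE)
  measured <- lapply(module_genes, function(g)
    sort(intersect(g, panel)))
  tab <- data.frame(module_id = names(module_genes),
                    n_genes = lengths(module_genes),
                    n_measured = lengths(measured),
                    stringsAsFactors = FALSE)
  tab$evaluable <- tab$n_measured >= params$min_measured_genes
  rownames(tab) <- NULL
  list(measured = measured, table = tab)
}

#' DEG fraction and activation call for one module in one condition
#'
#' Fraction of a module's measured genes that are differentially
#' expressed in the condition; the module is activated when the
#' fraction strictly exceeds the activation threshold ("more than 20%"
#' under the default).
#'
#' @param measured_genes measured gene ids of the module.
#' @param deg_table DEG data.frame with columns gene_id, is_deg.
#' @param params a [projection_params()].
#' @return list with `n_measured`, `n_deg`, `fraction`, `activated`,
#'   `evaluable`.
#' @export
deg_fraction <- function(measured_genes, deg_table,
                         params = projection_params()) {
  n_meas <- length(measured_genes)
  if (n_meas < params$min_measured_genes)
    return(list(n_measured = n_meas, n_deg = NA_integer_,
                fraction = NA_real_, activated = NA,
                evaluable = FALSE))
  flag <- deg_table$is_deg[match(measured_genes, deg_table$gene_id)]
  n_deg <- sum(flag, na.rm = TRUE)
  frac <- n_deg / n_meas
  list(n_measured = n_meas, n_deg = n_deg, fraction = frac,
       activated = frac > params$activation_fraction_threshold,
       evaluable = TRUE)
}

#' Projected module score
#'
#' Mean absolute log2 fold change over a module's measured genes,
#' regardless of DEG status -- the overall activation level of the
#' module in a condition.  With `weighting = "kme"` the mean is weighted
#' by the genes' module-membership values (weights normalized to sum 1).
#' Genes missing from the condition table are excluded and counted.
#'
#' @param measured_genes measured gene ids of the module.
#' @param deg_table DEG data.frame with columns gene_id, log2fc.
#' @param weighting `"plain"` or `"kme"`.
#' @param kme named kME vector (required for `"kme"` weighting).
#' @return list with `score`, `n_used`, `n_missing`, `evaluable`.
#' @export
module_score <- function(measured_genes, deg_table,
                         weighting = c("plain", "kme"), kme = NULL) {
  weighting <- match.arg(weighting)
  idx <- match(measured_genes, deg_table$gene_id)
  present <- !is.na(idx)
  lfc <- deg_table$log2fc[idx[present]]
  usable <- is.finite(lfc)
  lfc <- lfc[usable]
  genes <- measured_genes[present][usable]
  n_missing <- length(measured_genes) - length(genes)
  if (!length(genes))
    return(list(score = NA_real_, n_used = 0L, n_missing = n_missing,
                evaluable = FALSE))
  if (weighting == "kme") {
    if (is.null(kme)) stop("'kme' required for kme weighting",
                           call. = FALSE)
    w <- abs(kme[genes])
    if (any(is.na(w))) stop("missing kME for measured gene(s)",
                            call. = FALSE)
    w <- w / sum(w)
    score <- sum(w * abs(lfc))
  } else {
    score <- mean(abs(lfc))
  }
  list(score = score, n_used = length(genes), n_missing = n_missing,
       evaluable = TRUE)
}

#' Concentration trend of module scores
#'
#' Ordinary least squares of the module score on log10 concentration,
#' with a two-sided t-test on the slope and a 95% confidence interval.
#' The dose-responsive call requires a positive slope significant at
#' `alpha`.  With exactly two distinct concentrations the slope is
#' reported but the p-value is `NA` (no inference).
#'
#' @param scores module scores, one per condition.
#' @param concentrations matching positive concentrations.
#' @param alpha significance level, default 0.05.
#' @return list with `slope`, `se`, `ci_lower`, `ci_upper`, `p`,
#'   `dose_responsive`.
#' @export
concentration_trend <- function(scores, concentrations, alpha = 0.05) {
  if (length(scores) != length(concentrations))
    stop("'scores' and 'concentrations' lengths differ", call. = FALSE)
  if (any(concentrations <= 0))
    stop("'concentrations' must be positive", call. = FALSE)
  ok <- is.finite(scores)
  scores <- scores[ok]
  concentrations <- concentrations[ok]
  n_lev <- length(unique(concentrations))
  if (n_lev < 2)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  x <- log10(concentrations)
  fit <- stats::lm(scores ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (n_lev == 2 || length(scores) < 3) {
    return(list(slope = slope, se = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, p = NA_real_,
                dose_responsive = NA))
  }
  sm <- summary(fit)$coefficients
  se <- sm[2, 2]
  p <- sm[2, 4]
  tcrit <- stats::qt(0.975, fit$df.residual)
  list(slope = slope, se = se,
       ci_lower = slope - tcrit * se, ci_upper = slope + tcrit * se,
       p = p, dose_responsive = slope > 0 && p < alpha)
}

#' Recurrent DEGs of a module across a compound's concentrations
#'
#' Measured module genes that are differentially expressed in at least
#' two tested concentrations of the compound.
#'
#' @param measured_genes measured gene ids of the module.
#' @param deg_tables list of DEG data.frames, one per concentration of
#'   the compound (>= 2).
#' @return character vector of recurrent gene ids (sorted).
#' @export
recurrent_degs <- function(measured_genes, deg_tables) {
  if (length(deg_tables) < 2)
    stop("need >= 2 concentrations per compound", call. = FALSE)
  counts <- rowSums(vapply(deg_tables, function(tab) {
    flag <- tab$is_deg[match(measured_genes, tab$gene_id)]
    !is.na(flag) & flag
  }, logical(length(measured_genes))))
  sort(measured_genes[counts >= 2])
}

#' Project frozen modules onto per-condition DEG tables
#'
#' Full projection stage: panel restriction, per-condition DEG fractions
#' and activation calls, module scores, per-compound concentration
#' trends, and recurrent-DEG lists with cross-compound flags.
#'
#' @param module_genes named list of gene ids per module.
#' @param panel measured panel gene ids.
#' @param deg_tables named list of DEG data.frames, one per condition id.
#' @param manifest data.frame with columns condition_id, compound,
#'   concentration (ids matching `deg_tables` names).
#' @param params a [projection_params()].
#' @param kme optional named kME vector for `"kme"` score weighting.
#' @return list with `coverage` (panel-restriction table), `activation`
#'   (module x condition data.frame: n_measured, n_deg, fraction,
#'   activated, score), `trend` (module x compound data.frame with OLS
#'   slope, se, 95% CI, p, dose_responsive), `recurrent` (data.frame:
#'   module_id, compound, gene_id, cross_compound).
#' @export
project_modules <- function(module_genes, panel, deg_tables, manifest,
                            params = projection_params(), kme = NULL) {
  need <- c("condition_id", "compound", "concentration")
  if (!all(need %in% names(manifest)))
    stop("'manifest' needs columns condition_id, compound, concentration",
         call. = FALSE)
  miss <- setdiff(manifest$condition_id, names(deg_tables))
  if (length(miss))
    stop(sprintf("missing DEG table(s) for condition(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  restr <- restrict_to_panel(module_genes, panel, params)

  activation <- NULL
  for (m in names(restr$measured)) {
    for (ci in manifest$condition_id) {
      fr <- deg_fraction(restr$measured[[m]], deg_tables[[ci]], params)
      sc <- if (fr$evaluable)
        module_score(restr$measured[[m]], deg_tables[[ci]],
                     params$score_weighting, kme)$score
      else NA_real_
      activation <- rbind(activation, data.frame(
        module_id = m, condition_id = ci,
        compound = manifest$compound[manifest$condition_id == ci],
        concentration =
          manifest$concentration[manifest$condition_id == ci],
        n_measured = fr$n_measured, n_deg = fr$n_deg,
        fraction = fr$fraction, activated = fr$activated,
        score = sc, evaluable = fr$evaluable,
        stringsAsFactors = FALSE))
    }
  }

  trend <- NULL
  recurrent <- NULL
  for (cmp in unique(manifest$compound)) {
    conds <- manifest[manifest$compound == cmp, ]
    for (m in names(restr$measured)) {
      rows <- activation$module_id == m &
        activation$compound == cmp & activation$evaluable
      if (sum(rows) >= 2 &&
          length(unique(activation$concentration[rows])) >= 2) {
        tr <- concentration_trend(activation$score[rows],
                                  activation$concentration[rows],
                                  params$trend_alpha)
        trend <- rbind(trend, data.frame(
          module_id = m, compound = cmp, slope = tr$slope, se = tr$se,
          ci_lower = tr$ci_lower, ci_upper = tr$ci_upper, p = tr$p,
          dose_responsive = tr$dose_responsive,
          stringsAsFactors = FALSE))
      }
      if (nrow(conds) >= 2 && restr$table$evaluable[
        restr$table$module_id == m]) {
        rec <- recurrent_degs(restr$measured[[m]],
                              deg_tables[conds$condition_id])
        if (length(rec))
          recurrent <- rbind(recurrent, data.frame(
            module_id = m, compound = cmp, gene_id = rec,
            stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(recurrent)) {
    key <- paste(recurrent$module_id, recurrent$gene_id)
    n_cmp <- tapply(recurrent$compound, key,
                    function(x) length(unique(x)))
    recurrent$cross_compound <- unname(n_cmp[key] >= 2)
  }
  list(coverage = restr$table, activation = activation, trend = trend,
       recurrent = recurrent)
}
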