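#' Default in vitro compound set
#'
#' Five compounds mirroring the structure of the validation experiment:
#' three fibrosis-inducing compounds (diketone-like), one compound that
#' perturbs only inflammation-related modules (tunicamycin-like), and one
#' inert solvent (acetone-like).
#'
#' @return named character vector mapping compound name to class, one of
#'   `"fibrosis"`, `"inflammation"`, `"inert"`.
#' @export
default_compounds <- function() {
  c(diketone_A = "fibrosis",
    diketone_B = "fibrosis",
    diketone_C = "fibrosis",
    misfolder  = "inflammation",
    solvent    = "inert")
}

#' Build a targeted measurement panel over a simulated gene universe
#'
#' Emulates a reduced-representation assay panel: only a subset of each
#' module's genes is measured.  Default per-module coverages span 4 to 42
#' genes (the smallest coverage is placed on an inflammatory-profile
#' module, as in the motivating targeted-panel study), plus background
#' genes not in any module.
#'
#' @param truth truth labels from [simulate_invivo()] (list with
#'   `labels`).
#' @param coverage integer vector, measured genes per module, recycled
#'   across modules in plan order.
#' @param n_background number of background (non-module) panel genes.
#' @param seed integer seed for the panel draw.
#' @return character vector of panel gene ids.
#' @export
default_panel <- function(truth, coverage = c(42, 9, 4, 12, 17, 29, 25, 19),
                          n_background = 100, seed = 1L) {
  set.seed(derive_seed(seed, "panel"))
  mods <- setdiff(unique(truth$labels), "0")
  coverage <- rep_len(coverage, length(mods))
  panel <- character(0)
  for (i in seq_along(mods)) {
    members <- names(truth$labels)[truth$labels == mods[i]]
    k <- min(coverage[i], length(members))
    panel <- c(panel, sample(members, k))
  }
  bg <- names(truth$labels)[truth$labels == "0"]
  panel <- c(panel, sample(bg, min(n_background, length(bg))))
  sort(panel)
}

#' Simulate an in vitro targeted-panel concentration series
#'
#' Generates per-condition count matrices (treated vs control replicates)
#' for a panel of genes exposed to compounds at increasing
#' concentrations.  Planted log2 fold changes grow linearly with the
#' concentration rank: at the i-th of K ascending concentrations an
#' affected gene receives `|log2FC| = effect_size * i / K` (sign fixed
#' per gene).  Fibrosis-class compounds affect the panel genes of every
#' planted non-null module; inflammation-class compounds affect only
#' inflammatory-profile modules; inert compounds affect nothing.
#'
#' @param modules truth module structure: list with `labels`
#'   (gene-to-module, `"0"` = background) and `profiles` (module-to-phase
#'   profile).
#' @param panel character vector of measured gene ids; must be a subset
#'   of the simulated gene universe and non-empty, and every module must
#'   contribute at least one panel gene.
#' @param compounds named character vector of compound classes, see
#'   [default_compounds()].
#' @param concentrations positive, strictly increasing concentration
#'   levels (4 to 7 in the emulated design).
#' @param n_rep replicates per group (default 3 vs 3).
#' @param effect_size top-concentration |log2FC| for affected genes.
#' @param dispersion NB dispersion of the simulated counts.
#' @param seed integer seed.
#' @return list with `conditions` (one element per compound x
#'   concentration: `condition_id`, `compound`, `class`, `concentration`,
#'   `counts` genes x samples, `design`, `planted_lfc`) and `manifest`
#'   (data.frame: condition_id, compound, class, concentration).
#' @export
simulate_invitro <- function(modules, panel,
                             compounds = default_compounds(),
                             concentrations = c(0.1, 0.316, 1, 3.16, 10),
                             n_rep = 3, effect_size = 2,
                             dispersion = 0.1, seed = 1L) {
  if (!length(panel)) stop("'panel' must be non-empty", call. = FALSE)
  if (!all(panel %in% names(modules$labels)))
    stop("'panel' must be a subset of the simulated gene universe",
         call. = FALSE)
  if (any(concentrations <= 0) || is.unsorted(concentrations,
                                              strictly = TRUE))
    stop("'concentrations' must be positive and strictly increasing",
         call. = FALSE)
  mods <- setdiff(unique(modules$labels), "0")
  cover <- vapply(mods, function(m)
    sum(modules$labels[panel] == m), 1L)
  if (any(cover == 0))
    stop("every module must have at least one panel gene", call. = FALSE)
  .assert_scalar_number(n_rep, "n_rep", lower = 2, integer = TRUE)
  .assert_scalar_number(effect_size, "effect_size", lower = 0)
  set.seed(derive_seed(seed, "invitro"))

  K <- length(concentrations)
  base_log2 <- stats::runif(length(panel), 5, 9)
  names(base_log2) <- panel
  sign_g <- sample(c(-1, 1), length(panel), replace = TRUE)
  names(sign_g) <- panel
  panel_module <- modules$labels[panel]

  affected_modules <- function(class) {
    switch(class,
           fibrosis = mods[modules$profiles[mods] != "null"],
           inflammation = mods[modules$profiles[mods] == "inflammatory"],
           inert = character(0),
           stop(sprintf("unknown compound class '%s'", class),
                call. = FALSE))
  }

  conditions <- list()
  manifest <- NULL
  for (cmp in names(compounds)) {
    cls <- compounds[[cmp]]
    hit <- panel_module %in% affected_modules(cls)
    for (i in seq_len(K)) {
      lfc <- ifelse(hit, sign_g * effect_size * i / K, 0)
      names(lfc) <- panel
      mu_ctl <- 2^base_log2
      mu_trt <- 2^(base_log2 + lfc)
      counts <- cbind(
        matrix(stats::rnbinom(length(panel) * n_rep, mu = mu_trt,
                              size = 1 / dispersion),
               nrow = length(panel)),
        matrix(stats::rnbinom(length(panel) * n_rep, mu = mu_ctl,
                              size = 1 / dispersion),
               nrow = length(panel)))
      cid <- sprintf("%s_c%d", cmp, i)
      colnames(counts) <- sprintf("%s_%s%d", cid,
                                  rep(c("trt", "ctl"), each = n_rep),
                                  rep(seq_len(n_rep), 2))
      rownames(counts) <- panel
      design <- data.frame(sample_id = colnames(counts),
                           group = rep(c("treated", "control"),
                                       each = n_rep),
                           stringsAsFactors = FALSE)
      conditions[[cid]] <- list(condition_id = cid, compound = cmp,
                                class = cls,
                                concentration = concentrations[i],
                                counts = counts, design = design,
                                planted_lfc = lfc)
      manifest <- rbind(manifest,
                        data.frame(condition_id = cid, compound = cmp,
                                   class = cls,
                                   concentration = concentrations[i],
                                   stringsAsFactors = FALSE))
    }
  }
  list(conditions = conditions, manifest = manifest)
}
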