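# Orchestration: YAML config validation, staged pipeline driver, text
# report.  The numbered scripts under analysis/ are thin narrative
# wrappers over these functions.

#' Write a genes x samples matrix as TSV
#'
#' Genes in rows, first column `gene_id`, remaining columns named by
#' sample id.
#'
#' @param mat matrix with gene row names and sample column names.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples TSV written by [write_expression_tsv()]
#'
#' @param path input path.
#' @return numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write module assignments (gene, module, kME) as TSV
#'
#' @param module_set a `module_set`.
#' @param path output path.
#' @export
write_module_tsv <- function(module_set, path) {
  kme <- module_set$kme
  labs <- module_set$labels
  df <- data.frame(gene_id = names(labs), module_id = unname(labs),
                   stringsAsFactors = FALSE)
  df$kme <- kme$kme[match(df$gene_id, kme$gene_id)]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read module assignments written by [write_module_tsv()]
#'
#' @param path input path.
#' @return list with `labels` (named gene-to-module vector) and `kme`
#'   (named vector, may contain NA for unassigned genes).
#' @export
read_module_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         module_id = "character"))
  list(labels = stats::setNames(df$module_id, df$gene_id),
       kme = stats::setNames(df$kme, df$gene_id))
}

.default_config <- function() {
  list(seed = 1L,
       simulation = list(n_genes = 2000L, n_per_group = 8L,
                         noise_sd = 1, latent_sd = 0.5,
                         control_latent_sd = 0.1,
                         secondary_rms = 0.45, baseline = 0.1,
                         amplitude = 1.5),
       network = list(power = 4, min_module_size = 30L,
                      merge_cor_threshold = 0.75,
                      cut_method = "adaptive",
                      cut_height_quantile = 0.99, use_tom = TRUE),
       phase = list(da_threshold = 2.5),
       deg = list(padj_cut = 0.05, lfc_cut = 1.0),
       projection = list(activation_fraction_threshold = 0.20,
                         min_measured_genes = 3L, trend_alpha = 0.05))
}

#' Validate a run configuration
#'
#' Reads a YAML configuration (or accepts a list), fills defaults
#' (power 4, minimum module size 30, merge threshold 0.75, DA threshold
#' 2.5, activation fraction 0.20), and range-checks every parameter.
#' All violations are collected and reported together, each with its
#' configuration path.
#'
#' @param config path to a YAML file, a list, or `NULL` (defaults only).
#' @return validated configuration list of class `run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (file.exists(config) && file.size(config) > 0)
      yaml::read_yaml(config) else list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("'config' must be a list or YAML path",
                             call. = FALSE)
  cfg <- utils::modifyList(.default_config(), config)

  errors <- character(0)
  check <- function(value, path, lower, upper = Inf) {
    if (!is.numeric(value) || length(value) != 1 || !is.finite(value) ||
        value < lower || value > upper)
      errors <<- c(errors, sprintf("%s: must be a number in [%s, %s]",
                                   path, lower, upper))
  }
  check(cfg$network$power, "network.power", 1)
  check(cfg$network$min_module_size, "network.min_module_size", 2)
  check(cfg$network$merge_cor_threshold, "network.merge_cor_threshold",
        1e-8, 1 - 1e-8)
  check(cfg$network$cut_height_quantile, "network.cut_height_quantile",
        1e-8, 1 - 1e-8)
  check(cfg$phase$da_threshold, "phase.da_threshold", 0)
  check(cfg$deg$padj_cut, "deg.padj_cut", 1e-12, 1)
  check(cfg$deg$lfc_cut, "deg.lfc_cut", 0)
  check(cfg$projection$activation_fraction_threshold,
        "projection.activation_fraction_threshold", 1e-8, 1 - 1e-8)
  check(cfg$projection$min_measured_genes,
        "projection.min_measured_genes", 1)
  check(cfg$projection$trend_alpha, "projection.trend_alpha", 1e-8,
        1 - 1e-8)
  check(cfg$simulation$n_genes, "simulation.n_genes", 1)
  check(cfg$simulation$n_per_group, "simulation.n_per_group", 2)
  check(cfg$simulation$noise_sd, "simulation.noise_sd", 1e-12)
  check(cfg$seed, "seed", -.Machine$integer.max, .Machine$integer.max)
  if (length(errors))
    stop(paste(c("invalid configuration:", errors), collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the pipeline on synthetic data
#'
#' Chains the stages simulate, normalize/DEG, network detection,
#' phase differential activity, and in vitro projection on the
#' synthetic-data generator, writing each stage's table under `out_dir`
#' and a run manifest (configuration echo, package version, file
#' digests, per-stage row counts, warnings).  Identical configuration
#' and seed give byte-identical outputs.
#'
#' @param config a validated [validate_config()] result, or anything
#'   accepted by it.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "deg", "network", "phase", "project")`; prerequisite
#'   stages of a requested stage must have been run into the same
#'   `out_dir` previously or be requested together.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, out_dir = "fibromod_run",
                         stages = c("simulate", "deg", "network",
                                    "phase", "project")) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  manifest <- list(package_version =
                     as.character(utils::packageVersion("fibromod")),
                   config = unclass(cfg), stages = stages,
                   rows = list(), files = character(0))

  paths <- list(expr = file.path(out_dir, "expression.tsv"),
                design = file.path(out_dir, "design.tsv"),
                truth = file.path(out_dir, "truth.tsv"),
                deg = file.path(out_dir, "deg"),
                modules = file.path(out_dir, "modules.tsv"),
                eigengenes = file.path(out_dir, "eigengenes.tsv"),
                phase = file.path(out_dir, "phase_activity.tsv"),
                activation = file.path(out_dir, "projection_activation.tsv"),
                trend = file.path(out_dir, "projection_trend.tsv"))

  sim <- NULL; mset <- NULL
  if ("simulate" %in% stages) {
    sc <- simulation_config(
      n_genes = cfg$simulation$n_genes,
      module_plans = default_module_plans(
        amplitude = cfg$simulation$amplitude),
      n_per_group = cfg$simulation$n_per_group,
      noise_sd = cfg$simulation$noise_sd,
      latent_sd = cfg$simulation$latent_sd,
      control_latent_sd = cfg$simulation$control_latent_sd,
      secondary_rms = cfg$simulation$secondary_rms,
      baseline = cfg$simulation$baseline,
      seed = cfg$seed)
    sim <- simulate_invivo(sc)
    write_expression_tsv(sim$expr, paths$expr)
    utils::write.table(sim$design, paths$design, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    truth_df <- data.frame(gene_id = names(sim$truth$labels),
                           module_id = unname(sim$truth$labels),
                           stringsAsFactors = FALSE)
    utils::write.table(truth_df, paths$truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$rows$simulate <- nrow(sim$expr)
  }

  load_sim <- function() {
    if (is.null(sim)) {
      if (!file.exists(paths$expr))
        stop("stage prerequisite missing: run 'simulate' first (no ",
             paths$expr, ")", call. = FALSE)
      sim <<- list(expr = read_expression_tsv(paths$expr),
                   design = utils::read.delim(paths$design,
                                              stringsAsFactors = FALSE))
    }
    sim
  }

  if ("deg" %in% stages) {
    s <- load_sim()
    dir.create(paths$deg, showWarnings = FALSE)
    n_deg_rows <- 0L
    for (d in unique(s$design$day[s$design$group == "treated"])) {
      ct <- contrast(
        s$design$sample_id[s$design$day == d &
                             s$design$group == "treated"],
        s$design$sample_id[s$design$group == "control"],
        label = sprintf("day%d", as.integer(d)))
      tab <- differential_expression(s$expr, ct)
      tab <- call_degs(tab, cfg$deg$padj_cut, cfg$deg$lfc_cut)$table
      write_deg_table(tab, file.path(paths$deg,
                                     sprintf("deg_day%02d.tsv",
                                             as.integer(d))))
      n_deg_rows <- n_deg_rows + nrow(tab)
    }
    manifest$rows$deg <- n_deg_rows
  }

  if ("network" %in% stages) {
    s <- load_sim()
    np <- network_params(
      power = cfg$network$power,
      min_module_size = cfg$network$min_module_size,
      merge_cor_threshold = cfg$network$merge_cor_threshold,
      cut_method = cfg$network$cut_method,
      cut_height_quantile = cfg$network$cut_height_quantile,
      use_tom = cfg$network$use_tom)
    mset <- detect_modules(s$expr, np)
    if (length(mset$dropped))
      note("network: dropped %d zero-variance gene(s)",
           length(mset$dropped))
    write_module_tsv(mset, paths$modules)
    write_expression_tsv(mset$eigengenes, paths$eigengenes)
    manifest$rows$network <- length(mset$sizes)
  }

  if ("phase" %in% stages) {
    s <- load_sim()
    if (is.null(mset)) {
      if (!file.exists(paths$modules))
        stop("stage prerequisite missing: run 'network' first (no ",
             paths$modules, ")", call. = FALSE)
      stored <- read_module_tsv(paths$modules)
      eg <- compute_eigengenes(s$expr, stored$labels)
      hk <- hub_genes(s$expr, stored$labels, eg$eigengenes)
      sizes <- table(stored$labels[stored$labels != "0"])
      mset <- structure(list(labels = stored$labels,
                             eigengenes = eg$eigengenes,
                             variance_explained = eg$variance_explained,
                             sizes = stats::setNames(as.integer(sizes),
                                                     names(sizes)),
                             hubs = hk$hubs, kme = hk$kme),
                        class = "module_set")
    }
    rep <- withCallingHandlers(
      phase_activity_report(mset, phase_map(s$design),
                            cfg$phase$da_threshold),
      warning = function(w) {
        note("phase: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.table(rep, paths$phase, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$rows$phase <- nrow(rep)
  }

  if ("project" %in% stages) {
    if (!file.exists(paths$truth))
      stop("stage prerequisite missing: run 'simulate' first (no ",
           paths$truth, ")", call. = FALSE)
    s <- load_sim()
    truth_df <- utils::read.delim(paths$truth,
                                  stringsAsFactors = FALSE,
                                  colClasses = "character")
    truth <- list(labels = stats::setNames(truth_df$module_id,
                                           truth_df$gene_id))
    truth$profiles <- stats::setNames(
      vapply(default_module_plans(), `[[`, "", "phase_profile"),
      vapply(default_module_plans(), `[[`, "", "module_id"))
    panel <- default_panel(truth, seed = cfg$seed)
    vitro <- simulate_invitro(truth, panel, seed = cfg$seed)
    deg_tables <- lapply(vitro$conditions, function(cond) {
      norm <- cpm_log_normalize(cond$counts + 0)
      ct <- contrast(cond$design$sample_id[cond$design$group ==
                                             "treated"],
                     cond$design$sample_id[cond$design$group ==
                                             "control"])
      call_degs(differential_expression(norm, ct),
                cfg$deg$padj_cut, cfg$deg$lfc_cut)$table
    })
    pp <- projection_params(
      activation_fraction_threshold =
        cfg$projection$activation_fraction_threshold,
      min_measured_genes = cfg$projection$min_measured_genes,
      trend_alpha = cfg$projection$trend_alpha)
    proj <- project_modules(module_gene_lists(truth$labels), panel,
                            deg_tables, vitro$manifest, pp)
    utils::write.table(proj$activation, paths$activation, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(proj$trend, paths$trend, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$rows$project <- nrow(proj$activation)
  }

  written <- Filter(function(p) file.exists(p) && !dir.exists(p),
                    unlist(paths))
  manifest$files <- as.list(tools::md5sum(written))
  manifest$warnings <- warnings_log
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Human-readable run summary
#'
#' Writes (and returns) a text report over the artifacts of a
#' [run_pipeline()] output directory: module table, differential
#' activity and selection, and the per-compound activation matrix.
#' Missing artifacts are marked absent rather than failing, so partial
#' runs still report.
#'
#' @param out_dir pipeline output directory.
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly if `path` given.
#' @export
write_report <- function(out_dir, path = NULL) {
  lines <- c("fibromod run report", strrep("=", 19), "")
  phase_file <- file.path(out_dir, "phase_activity.tsv")
  if (file.exists(phase_file)) {
    ph <- utils::read.delim(phase_file, stringsAsFactors = FALSE)
    lines <- c(lines,
               sprintf("Modules: %d (selected: %d)", nrow(ph),
                       sum(ph$selected)), "",
               "Differential activity (DA) per phase:",
               utils::capture.output(print(
                 ph[, grep("^module_id$|^DA_|^selected$|^assigned",
                           names(ph))], row.names = FALSE)), "")
  } else {
    lines <- c(lines, "Phase-activity section: absent", "")
  }
  act_file <- file.path(out_dir, "projection_activation.tsv")
  if (file.exists(act_file)) {
    act <- utils::read.delim(act_file, stringsAsFactors = FALSE)
    act_mat <- with(act[act$evaluable & !is.na(act$activated), ],
                    tapply(activated, list(module_id, compound), sum))
    lines <- c(lines, "Activated concentration levels per module x compound:",
               utils::capture.output(print(act_mat)), "")
  } else {
    lines <- c(lines, "Projection/activation section: absent", "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
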