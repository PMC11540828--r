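#' Planted-module plan
#'
#' Describes one co-expression module to be planted into a synthetic
#' in vivo time course: its size, the disease phase in which its latent
#' activity peaks, the latent effect size, and the range of absolute
#' per-gene loadings on the latent activity.
#'
#' @param module_id module label (coerced to character).
#' @param size number of member genes; at least 30, matching the minimum
#'   module size used at detection.
#' @param phase_profile one of `"inflammatory"`, `"acute"`, `"late"`,
#'   `"general"`, `"null"`.
#' @param amplitude latent effect size in log2 units (>= 0).  A `"null"`
#'   profile requires amplitude 0.
#' @param loading_range length-2 interval for absolute per-gene loadings.
#' @return an object of class `module_plan`.
#' @export
module_plan <- function(module_id, size, phase_profile,
                        amplitude = 1.5, loading_range = c(0.4, 0.9)) {
  .assert_scalar_number(size, "size", lower = 30, integer = TRUE)
  phase_profile <- match.arg(phase_profile,
                             c("inflammatory", "acute", "late",
                               "general", "null"))
  .assert_scalar_number(amplitude, "amplitude", lower = 0)
  if (phase_profile == "null" && amplitude != 0)
    stop("a 'null' phase_profile requires amplitude 0", call. = FALSE)
  if (length(loading_range) != 2L || any(!is.finite(loading_range)) ||
      loading_range[1] > loading_range[2])
    stop("'loading_range' must be an ordered length-2 interval",
         call. = FALSE)
  structure(list(module_id = as.character(module_id),
                 size = as.integer(size),
                 phase_profile = phase_profile,
                 amplitude = amplitude,
                 loading_range = as.numeric(loading_range)),
            class = "module_plan")
}

#' Default planted-module plan
#'
#' Eight phase-specific modules (three inflammatory, three
#' acute-fibrotic, two late-fibrotic) with sizes between 58 and 250
#' genes, mirroring the size range of phase-associated modules reported
#' for bleomycin-induced lung fibrosis.  The per-phase counts keep each
#' phase group within the dimension of its orthogonal
#' secondary-signature space, so every planted module is identifiable
#' by construction.
#'
#' @param amplitude latent effect size shared by all modules.
#' @param loading_range shared loading interval.
#' @return list of [module_plan()] objects.
#' @export
default_module_plans <- function(amplitude = 1.5,
                                 loading_range = c(0.4, 0.9)) {
  sizes <- c(250L, 86L, 83L, 58L, 100L, 167L, 149L, 123L)
  profiles <- c("inflammatory", "inflammatory", "inflammatory",
                "acute", "acute", "acute", "late", "late")
  mapply(function(i, s, p)
    module_plan(paste0("M", i), s, p, amplitude, loading_range),
    seq_along(sizes), sizes, profiles, SIMPLIFY = FALSE)
}

#' Simulation configuration for the in vivo time course
#'
#' Bundles all parameters of the synthetic treated-versus-control mouse
#' time course.  Defaults mirror the bleomycin study design: seven
#' sampling days (1, 2, 7, 14, 21, 28, 35) and eight animals per group
#' per day.
#'
#' @param n_genes total gene universe size.
#' @param module_plans list of [module_plan()] objects; their sizes must
#'   sum to at most `n_genes`.
#' @param timepoints sampling days.
#' @param n_per_group replicates per group per day (>= 2).
#' @param noise_sd per-gene residual standard deviation (> 0), log2 scale.
#' @param latent_sd standard deviation of the shared per-sample latent
#'   activity noise in treated animals, as a fraction of the module
#'   amplitude: animal-to-animal variability in the response to the
#'   insult (disease severity varies between treated animals).
#' @param control_latent_sd latent activity noise of control animals;
#'   much smaller than `latent_sd` (untreated animals are homogeneous),
#'   but non-zero so control samples achieve non-zero module activity.
#' @param baseline off-phase latent activity level (see
#'   [phase_trajectory()]); used for `"general"` and `"null"` profiles.
#' @param secondary_rms root-mean-square per-day magnitude of the
#'   signed secondary (off-primary-phase) activity signatures; see
#'   [simulate_invivo()].
#' @param primary_jitter scale of the asymmetric uniform jitter of the
#'   activity on primary-phase days: values are drawn from
#'   `U(1 - 0.4 j, 1 + 1.6 j)`, skewed above 1 so the weakest primary
#'   day stays clear of any secondary activity.
#' @param count_mode if `TRUE`, values are emitted as negative-binomial
#'   counts around `2^(baseline_log2 + signal)`; if `FALSE` (default),
#'   log2-scale intensities are returned directly.
#' @param dispersion NB dispersion used when `count_mode = TRUE`.
#' @param seed global integer seed for the run.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              module_plans = default_module_plans(),
                              timepoints = c(1, 2, 7, 14, 21, 28, 35),
                              n_per_group = 8,
                              noise_sd = 1,
                              latent_sd = 0.5,
                              control_latent_sd = 0.1,
                              baseline = 0.1,
                              secondary_rms = 0.45,
                              primary_jitter = 0.25,
                              count_mode = FALSE,
                              dispersion = 0.1,
                              seed = 1L) {
  .assert_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  if (!length(module_plans) ||
      !all(vapply(module_plans, inherits, TRUE, "module_plan")))
    stop("'module_plans' must be a non-empty list of module_plan objects",
         call. = FALSE)
  total <- sum(vapply(module_plans, `[[`, 1L, "size"))
  if (total > n_genes)
    stop(sprintf("module sizes (%d) exceed n_genes (%d)", total, n_genes),
         call. = FALSE)
  .assert_scalar_number(n_per_group, "n_per_group", lower = 2,
                        integer = TRUE)
  .assert_scalar_number(noise_sd, "noise_sd", lower = 1e-12)
  .assert_scalar_number(latent_sd, "latent_sd", lower = 0)
  .assert_scalar_number(control_latent_sd, "control_latent_sd",
                        lower = 0)
  .assert_scalar_number(baseline, "baseline", lower = 0, upper = 1)
  .assert_scalar_number(secondary_rms, "secondary_rms", lower = 0,
                        upper = 1)
  .assert_scalar_number(primary_jitter, "primary_jitter", lower = 0,
                        upper = 0.5)
  .assert_scalar_number(dispersion, "dispersion", lower = 1e-12)
  .assert_scalar_number(seed, "seed", integer = TRUE)
  if (!length(timepoints) || any(timepoints <= 0))
    stop("'timepoints' must be positive days", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 module_plans = module_plans,
                 timepoints = as.numeric(timepoints),
                 n_per_group = as.integer(n_per_group),
                 noise_sd = noise_sd,
                 latent_sd = latent_sd,
                 control_latent_sd = control_latent_sd,
                 baseline = baseline,
                 secondary_rms = secondary_rms,
                 primary_jitter = primary_jitter,
                 count_mode = isTRUE(count_mode),
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Latent phase activity trajectory
#'
#' Activity of a module's latent driver on a given treated day.  A
#' profile is fully active (1) during its phase -- inflammatory on days
#' 1-2, acute-fibrotic on days 7-14, late-fibrotic from day 21 onwards --
#' and sits at a small off-phase baseline otherwise, so that phase
#' *specificity* (not mere on/off behaviour) is what downstream scoring
#' must resolve.  A `"general"` profile is active on every treated day;
#' a `"null"` profile is 0 everywhere.
#'
#' @param profile phase profile label.
#' @param day treated day (vectorized); must be positive.
#' @param baseline off-phase activity level, default 0.1.
#' @return numeric vector of activities in \[0, 1\].
#' @export
phase_trajectory <- function(profile, day, baseline = 0.1) {
  profile <- match.arg(profile, c("inflammatory", "acute", "late",
                                  "general", "null"))
  .assert_scalar_number(baseline, "baseline", lower = 0, upper = 1)
  if (any(!is.finite(day)) || any(day <= 0))
    stop("'day' must be positive", call. = FALSE)
  on <- switch(profile,
               inflammatory = day <= 2,
               acute        = day >= 7 & day <= 14,
               late         = day >= 21,
               general      = rep(TRUE, length(day)),
               null         = rep(FALSE, length(day)))
  if (profile == "null") return(rep(0, length(day)))
  ifelse(on, 1, baseline)
}

#' Phase label for a treated day
#'
#' Maps treated days onto the histopathologically defined phases:
#' days 1-2 inflammatory, days 7-14 acute fibrotic, day 21 onwards late
#' fibrotic.
#'
#' @param day numeric vector of treated days.
#' @return character vector of phase labels.
#' @export
day_to_phase <- function(day) {
  ifelse(day <= 2, "inflammatory", ifelse(day < 21, "acute", "late"))
}

#' Simulate an in vivo treated-versus-control time course
#'
#' Generates a gene-by-sample expression matrix with planted
#' co-expression modules.  Each module has a latent activity over the
#' design: near 1 (jittered by `primary_jitter`) on the days of its
#' primary phase, a module-specific signed secondary activity on every
#' other treated day, and 0 in controls.  Secondary signatures are what
#' distinguishes modules sharing a primary phase -- without them,
#' same-phase modules would be perfectly co-expressed and no
#' correlation-based method could tell them apart; they emulate the
#' wide per-module spread of off-phase differential activity seen in
#' real phase-assigned modules.  Within each phase group the secondary
#' day-vectors are drawn as random mutually orthogonal zero-sum vectors
#' with per-day RMS `secondary_rms`, so distinct planted modules are
#' identifiable by construction (orthogonal signatures) and the
#' design-mean activity of every module is fixed by its phase alone.
#'
#' A treated sample at day `t` then receives
#' `z = amplitude * (activity(t) + e)` with `e ~ N(0, latent_sd)`
#' (animal-to-animal variability in response severity) and a control
#' sample `z = amplitude * e0` with the smaller
#' `e0 ~ N(0, control_latent_sd)`, each shared by all member
#' genes of the sample; member gene
#' values are `loading * z + N(0, noise_sd)` with loadings of random
#' sign drawn from `loading_range` (modules mix positively and
#' negatively correlated genes).  Background genes are pure noise.  With
#' `count_mode = TRUE` the log2-scale signal is converted to
#' negative-binomial counts.
#'
#' @param config a [simulation_config()].
#' @return list with elements `expr` (genes x samples matrix), `design`
#'   (data.frame: sample_id, day, group, phase) and `truth` (list:
#'   `labels` gene-to-module character vector, `"0"` for background;
#'   `profiles` named per-module phase profiles; `secondary` per-module
#'   secondary-activity draws; `plans` the input plans).
#' @export
simulate_invivo <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a simulation_config()", call. = FALSE)
  set.seed(derive_seed(config$seed, "invivo"))

  tp <- config$timepoints
  n <- config$n_per_group
  n_samp <- 2L * n * length(tp)
  day <- rep(tp, each = 2L * n)
  group <- rep(rep(c("treated", "control"), each = n), times = length(tp))
  sample_id <- sprintf("d%02d_%s_%d", as.integer(day),
                       ifelse(group == "treated", "trt", "ctl"),
                       rep(seq_len(n), times = 2L * length(tp)))
  design <- data.frame(sample_id = sample_id, day = day, group = group,
                       phase = ifelse(group == "control", "control",
                                      day_to_phase(day)),
                       stringsAsFactors = FALSE)

  gene_id <- sprintf("g%04d", seq_len(config$n_genes))
  expr <- matrix(stats::rnorm(config$n_genes * n_samp,
                              sd = config$noise_sd),
                 nrow = config$n_genes, ncol = n_samp,
                 dimnames = list(gene_id, sample_id))

  phases3 <- c("inflammatory", "acute", "late")
  treated <- design$group == "treated"
  sample_phase <- ifelse(treated, day_to_phase(design$day), "control")

  # Secondary signatures: per phase group, random mutually orthogonal
  # zero-sum day-vectors over the off-phase days (Gram-Schmidt on
  # mean-centred Gaussian draws), scaled to per-day RMS secondary_rms.
  plan_profiles <- vapply(config$module_plans, `[[`, "", "phase_profile")
  plan_ids <- vapply(config$module_plans, `[[`, "", "module_id")
  secondary_sig <- list()
  plan_sizes <- vapply(config$module_plans, `[[`, 1L, "size")
  for (ph in phases3) {
    members <- plan_ids[plan_profiles == ph]
    if (!length(members)) next
    # orthogonalize small modules first: if the group exceeds the free
    # dimension, the leftover (non-orthogonal) signature lands on the
    # largest module, which tolerates residual correlation best
    members <- members[order(plan_sizes[match(members, plan_ids)])]
    off_days <- tp[day_to_phase(tp) != ph]
    d <- length(off_days)
    off_phase <- day_to_phase(off_days)
    # signatures are zero-sum within every off phase, so a module's
    # secondary activity cannot align with another phase's primary
    # indicator (cross-phase decorrelation by construction)
    center_phase <- function(v) {
      for (p in unique(off_phase))
        v[off_phase == p] <- v[off_phase == p] -
          mean(v[off_phase == p])
      v
    }
    free_dim <- d - length(unique(off_phase))
    basis <- matrix(0, 0, d)
    for (m in members) {
      v <- center_phase(stats::rnorm(d))
      if (nrow(basis) < free_dim) {            # orthogonalize if room
        repeat {
          if (nrow(basis)) v <- v - drop(t(basis) %*% (basis %*% v))
          if (sqrt(sum(v^2)) > 1e-6) break
          v <- center_phase(stats::rnorm(d))
        }
        basis <- rbind(basis, v / sqrt(sum(v^2)))
      }
      sig <- v / sqrt(sum(v^2)) * config$secondary_rms * sqrt(d)
      # cap secondaries so no off phase can rival the primary phase in
      # mean absolute activity: per-day values at most 0.5 and
      # per-phase mean absolute activity at most 0.38
      sig <- sig * min(1, 0.5 / max(abs(sig)))
      for (p in unique(off_phase)) {
        mp <- mean(abs(sig[off_phase == p]))
        if (mp > 0.38) sig <- sig * 0.38 / mp
      }
      secondary_sig[[m]] <- stats::setNames(sig, off_days)
    }
  }

  labels <- rep("0", config$n_genes)
  profiles <- character(0)
  secondary <- list()
  next_gene <- 1L
  for (plan in config$module_plans) {
    idx <- next_gene:(next_gene + plan$size - 1L)
    next_gene <- next_gene + plan$size
    labels[idx] <- plan$module_id
    profiles[plan$module_id] <- plan$phase_profile
    loadings <- stats::runif(plan$size, plan$loading_range[1],
                             plan$loading_range[2]) *
      sample(c(-1, 1), plan$size, replace = TRUE)

    if (plan$phase_profile %in% phases3) {
      on_days <- tp[day_to_phase(tp) == plan$phase_profile]
      off_days <- setdiff(tp, on_days)
      # asymmetric jitter (skewed above 1) keeps the weakest primary
      # day well above any capped secondary
      day_act <- c(
        stats::setNames(stats::runif(length(on_days),
                                     1 - 0.4 * config$primary_jitter,
                                     1 + 1.6 * config$primary_jitter),
                        on_days),
        secondary_sig[[plan$module_id]])
      activity <- ifelse(treated, day_act[as.character(design$day)], 0)
      secondary[[plan$module_id]] <- day_act
    } else {
      traj <- phase_trajectory(plan$phase_profile, design$day,
                               config$baseline)
      activity <- ifelse(treated, traj, 0)
      secondary[[plan$module_id]] <- stats::setNames(
        phase_trajectory(plan$phase_profile, tp, config$baseline), tp)
    }
    lat_sd <- ifelse(treated, config$latent_sd,
                     config$control_latent_sd)
    z <- plan$amplitude *
      (activity + stats::rnorm(n_samp) * lat_sd)
    expr[idx, ] <- expr[idx, ] + outer(loadings, z)
  }
  names(labels) <- gene_id

  if (config$count_mode) {
    base_log2 <- stats::runif(config$n_genes, 5, 9)
    mu <- 2^(base_log2 + expr)
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / config$dispersion),
                  nrow = nrow(expr), dimnames = dimnames(expr))
    expr <- cnt
  }

  list(expr = expr, design = design,
       truth = list(labels = labels, profiles = profiles,
                    secondary = secondary,
                    plans = config$module_plans))
}
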