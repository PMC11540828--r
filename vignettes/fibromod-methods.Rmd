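---
title: "Phase-specific co-expression biomarker modules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-specific co-expression biomarker modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chemically induced lung fibrosis develops through histopathologically
distinct stages: an inflammatory phase in the first days after insult,
an acute fibrotic phase with fibroblast infiltration and collagen
deposition around days 7--14, and a late fibrotic phase of
extracellular-matrix remodelling from about day 21 onwards.  Groups of
co-expressed genes whose joint activity peaks in one of these phases
are candidate *composite biomarkers*: applied to a new experiment --
for example a targeted-panel concentration series on airway epithelial
cells -- they indicate whether a compound engages fibrosis-related
transcriptional programmes, and in which stage-specific flavour.

`fibromod` implements this derivation end to end: weighted gene
co-expression network analysis on a treated-versus-control mouse time
course, a phase-wise differential-activity statistic for module
selection, annotation of the selected modules, and projection of the
frozen modules onto external per-condition differential-expression
tables.  A synthetic-data generator with known planted structure stands
in for the original study data, so every stage is testable offline.

# Network construction and module detection

Expression is normalised to counts per million and `log2(x + 1)`
transformed (`cpm_log_normalize()`; the pseudocount of 1 is a standard,
invertible choice).  Genes without variance are removed with a logged
manifest.  The network is *unsigned*: adjacency is
`a_ij = |cor_ij|^beta` with soft threshold `beta = 4`
(`network_params(power = 4)`), because modules are meant to group
highly positively *or* negatively correlated genes.  Pearson
correlation is the default; Spearman is available.
`pick_soft_threshold()` reports the signed scale-free fit index
`R^2` and mean connectivity per candidate power, the tabular
counterpart of choosing the power graphically.

Clustering uses average linkage on the topological-overlap
dissimilarity `1 - TOM` by default (`use_tom = TRUE`), switchable to
`1 - |cor|^beta`; the TOM credits shared neighbourhoods and is the
standard companion of soft-threshold adjacency.

## Tree cutting

`cut_tree_dynamic()` cuts the dendrogram at a single height.  Two
strategies are provided:

* `"adaptive"` (default): among all candidate heights (just above each
  merge), choose the lowest one that maximises the number of branches
  with at least `min_module_size` members.  This adapts the cut to the
  tree instead of fixing a quantile, and is robust to the absolute
  scale of TOM dissimilarities, which typically compresses into a
  narrow band below 1.
* `"quantile"`: a static cut at a fixed quantile (default 0.99) of the
  merge heights.  In our simulations this static rule either left
  large background branches intact or fragmented weak modules -- there
  is usually no single quantile that serves both -- so it is kept as
  an option but not used by default.

`detect_modules()` embeds the cut in a refinement loop that mirrors
the logic of dynamic branch cutting:

1. **Seeding.** Branches are accepted at half the final minimum module
   size (at least 5).  Weak modules often present only a tight core at
   the cut height; the core is grown afterwards, and any module still
   below `min_module_size` at the end is discarded.
2. **Noise gate.** A candidate branch is accepted only if its
   eigengene explains at least `ve_gate` (default 2) times the
   Marchenko--Pastur expectation `(1 + sqrt(m/n))^2 / m` for `m`
   independent genes over `n` samples.  Clustered noise selected by
   the dendrogram reaches about 1.2--1.7 times that expectation in our
   simulations, genuine planted modules 3 times and more, so the gate
   separates them with a wide margin and, importantly, leaves pure
   noise data with *no* modules at all.
3. **Splitting.** Each accepted branch is re-clustered on its own;
   if it decomposes into two or more gate-passing sub-branches it is
   replaced by them.  Over-splitting of a genuine module is harmless
   because the merge step below re-fuses halves of one module (their
   eigengenes correlate far above the merge threshold).
4. **Membership attachment and rescue.** Unassigned genes whose best
   absolute module membership (|kME|, the correlation with a module
   eigengene) reaches `pam_kme_threshold` (default 0.26) are attached
   to that module; the remaining unassigned genes are re-clustered so
   a module that fragmented at the global cut height can still
   surface.  This alternation runs to a fix point.
5. **Merging and sweep.** Modules with eigengene correlation above
   `merge_cor_threshold` (default 0.75) are merged iteratively,
   recomputing eigengenes after every merge.  A global kME sweep then
   reassigns every gene to its best-matching module (or to none),
   which removes background contamination picked up by branches; a
   final merge and size filter follow.

Eigengenes are the first right-singular vector of the per-gene
standardized module submatrix: one entry per sample, unit Euclidean
norm, sign-oriented so the mean correlation with member genes is
non-negative (ties broken so the first member gene correlates
positively).  The hub gene maximises kME, with lexicographic
tie-breaking.

# Phase-wise differential activity

Samples map to phase classes: treated days 1--2 are inflammatory, 7--14
acute, 21 and later late; all control samples pool into one control
class.  The activity of module *m* in phase *P* is the mean *absolute*
eigengene entry over the phase's samples,

    EG(m, P) = mean_{s in P} |e_m(s)|,

and the differential activity is the ratio to control activity,

    DA(m, P) = EG(m, P) / max(EG(m, control), 1e-8).

Control samples achieve non-zero activity (they sit away from the
grand mean of the standardized data), so DA near 1 means "no different
from control".  A control score below the `1e-8` guard is flagged
unstable with a warning.  DA is invariant to positive rescaling of the
eigengene.  Modules reaching `DA >= 2.5` in any phase are selected and
assigned to every phase reaching the threshold; the threshold is
inclusive because the printed convention in the motivating analysis
counts a DA of exactly 2.50 as active.  No significance test is
attached to DA -- it is a plain threshold statistic by design.

# Annotation

Selected modules are translated to a target gene namespace through a
static two-column ortholog table (one-to-many mappings expand to all
targets, deduplicated per module; unmapped genes are dropped and
counted).  Biomarker overlap is an exact identifier intersection.
Gene-set over-representation uses the one-sided Fisher exact
(hypergeometric upper-tail) p-value on the 2x2 in-module x in-set
table, with Benjamini--Hochberg adjustment across sets within each
module.  The enrichment universe is the set of genes that entered the
network (not the whole genome), because the background should match
the tested pool; it is a function argument and can be widened.  The
files bundled under `inst/extdata/` (ortholog map, biomarker list,
GO-style sets) are *synthetic* stand-ins so examples and tests run
offline; real analyses should substitute exports from the usual
databases.

# Projection onto targeted panels

Frozen modules are intersected with the measured panel
(`restrict_to_panel()`); modules with fewer than `min_measured_genes`
(default 3) measured genes are flagged not evaluable -- a guard
against one-gene "modules" on small panels.  Two complementary
read-outs follow:

* **DEG fraction.** The fraction of a module's measured genes that are
  differentially expressed in a condition; the module is *activated*
  when the fraction strictly exceeds 0.20 ("more than 20%").  This
  read-out is robust to reduced panel coverage.
* **Module score.** The mean absolute log2 fold change over all
  measured module genes, DEG or not -- the overall activation level.
  A kME-weighted variant is provided (`score_weighting = "kme"`)
  because eigengene-based scoring weights genes by membership, but the
  unweighted mean is the default read-out.  Scores are regressed on
  log10 concentration by ordinary least squares;
  a *dose-responsive* call requires a positive slope significant at
  `trend_alpha = 0.05` (two-sided t-test, 95% confidence interval
  reported).  With exactly two distinct concentrations the slope is
  reported without inference.  "Dose-responsive" is this package's
  operational criterion; the motivating analysis described the pattern
  only qualitatively.

Genes differentially expressed at two or more concentrations of a
compound are listed as recurrent DEGs, with genes recurrent for more
than one compound flagged.

# The synthetic-data generator

`simulate_invivo()` emulates the bleomycin study design: seven
sampling days (1, 2, 7, 14, 21, 28, 35), eight treated and eight
control mice per day (112 samples), 2,000 genes with eight planted
modules of 58--250 genes (three inflammatory, three acute, two late).
Each module has a latent activity per treated day: jittered around 1
on its primary-phase days and a signed module-specific *secondary*
activity on every other day.  A treated sample receives
`z = amplitude * (activity(day) + e)` with `e ~ N(0, latent_sd)`; a
control sample receives `z = amplitude * e0` with the smaller
`e0 ~ N(0, control_latent_sd)`.  Member genes load on `z` with random
sign and magnitude in `loading_range`, plus `N(0, noise_sd)` residual
noise; background genes are pure noise.  Defaults: amplitude 1.5,
loadings 0.4--0.9, `noise_sd` 1, `latent_sd` 0.5, `control_latent_sd`
0.1, `secondary_rms` 0.45.

Several generator choices deserve explanation:

* **Secondary activities.** If all same-phase modules shared one
  deterministic trajectory they would be mutually correlated near 1,
  and *no* correlation-based method could separate them -- the truth
  itself would be ill-posed.  Real phase-assigned modules show widely
  varying off-phase activity (off-phase DA from well below to just
  under the selection threshold), i.e. distinct secondary behaviour.
  The generator therefore draws, per phase group, mutually orthogonal
  zero-sum day-vectors (zero-sum within every off phase, so a
  module's secondary activity cannot align with another phase's
  primary indicator), scaled to per-day RMS `secondary_rms` and capped
  (per-day 0.5, per-phase mean 0.38) so no off phase can rival the
  primary phase.  The default plan keeps each phase group within the
  dimension of its orthogonal signature space (3/3/2), which makes all
  eight planted modules identifiable by construction.
* **Treated-only latent noise.** Animal-to-animal variability in
  disease severity is a treated-animal phenomenon; control animals
  are comparatively homogeneous.  Modelling it this way decorrelates
  same-phase modules (each module's severity noise is independent)
  without inflating control activity, keeping the primary-phase DA of
  planted modules comfortably above the 2.5 threshold.
* **Primary-day jitter** is asymmetric (`U(1 - 0.4 j, 1 + 1.6 j)`,
  default j = 0.25) so the weakest primary day stays clear of any
  capped secondary -- this protects the identity of each module's
  most-active phase.

`simulate_invitro()` emulates a targeted-panel concentration series:
per-module panel coverage of 4--42 genes (the smallest coverage placed
on an inflammatory module, as in the motivating panel), five
concentrations spanning two decades, 3 vs 3 replicates of
negative-binomial counts (dispersion 0.1).  Affected genes receive
planted `|log2FC| = effect_size * i / K` at the i-th of K ascending
concentrations (default top effect 2).  Fibrosis-class compounds shift
every planted module, inflammation-class compounds only
inflammatory-profile modules, inert compounds nothing.

What the generator does *not* emulate -- and hence what passing tests
do not establish about real data: probe-level microarray artefacts,
batch effects, cell-type composition shifts, non-linear dose-response
shapes, and correlated residual noise between modules.  Recovery
results on this generator demonstrate the pipeline's correctness and
calibration under the planted model, not field performance.

# Numerical choices and degenerate inputs

* Welch t-test on log-CPM as the built-in DE engine (vectorized means,
  variances and Welch--Satterthwaite degrees of freedom); zero
  variance in both groups yields p = 1 when means agree and p = 0
  otherwise.  External DEG tables are accepted and re-thresholded.
* DEG thresholds: adjusted p < 0.05 (strict) and |log2FC| >= 1
  (inclusive); the inclusive fold-change bound follows the stated
  methods convention over the figure-caption wording.
* BH adjustment delegates to `stats::p.adjust`; re-adjusting already
  adjusted p-values is undefined and not done anywhere.
* Ties: hub genes break ties lexicographically; module merging picks
  the lowest module indices among equally correlated pairs; the
  adaptive cut picks the lowest optimal height.  All randomness flows
  from one global seed through `derive_seed()` (stage-tagged
  sub-seeds, always below 2^31), so identical configuration and seed
  give byte-identical outputs.
* Degenerate networks (all-equal connectivity) report a scale-free
  R^2 of 0 with a warning rather than failing.

# Problem sizes used in tests

The test-suite simulations use the full study-shaped design (2,000
genes x 112 samples) for ten seeds in the planted-recovery and
phase-activity checks, a reduced 500-gene design for one hundred
null-data runs, and ten seeds of the in vitro series (about 260 panel
genes x 25 conditions).  These sizes were chosen to keep the whole
suite comfortably reproducible on a laptop while leaving the study's
per-run design (samples per group, timepoints, module sizes) intact.

# Known limitations

* The dynamic-cut realization is a deliberately simplified relative of
  the reference dynamic tree cut; it is validated by planted-structure
  recovery, not by label equality with that implementation.
* The DA statistic has no attached significance test; its false-positive
  behaviour is characterised empirically on null simulations instead.
* Enrichment depends entirely on the supplied gene-set files; the
  bundled sets are synthetic.
* With mean-centred eigengenes and a balanced design, a module elevated
  uniformly across *all* treated days has DA near 1 by construction;
  such "general" modules are expressible in the generator but cannot be
  selected by the DA rule, which is why the default plan uses
  phase-specific modules only.
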