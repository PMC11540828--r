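# fibromod

Phase-specific gene co-expression modules as composite biomarkers of
chemically induced lung fibrosis.

Lung fibrosis induced by compounds such as bleomycin progresses through
an inflammatory phase (days 1–2 after insult), an acute fibrotic phase
(days 7–14) and a late fibrotic phase (day 21 onwards).  `fibromod`
derives groups of co-expressed genes (modules) whose activity peaks in
one of these phases from a treated-versus-control time course, and
applies the frozen modules to external concentration-response
transcriptomics to flag compounds that engage fibrosis-related
programmes.  The package is aimed at toxicogenomics analysts building
or evaluating such composite biomarkers.

## The method in brief

1. **Network.** Log-CPM expression; unsigned weighted network
   `a_ij = |cor(x_i, x_j)|^β` with soft threshold β = 4; topological
   overlap (TOM) dissimilarity; average-linkage clustering; adaptive
   tree cut with minimum module size 30; eigengene-correlation merging
   at r > 0.75.  The module **eigengene** is the first principal
   component of the standardized module submatrix; the **hub gene**
   correlates most strongly with it.
2. **Phase activity.** For module *m* and phase *P*,
   `EG(m,P) = mean_{s∈P} |e_m(s)|` and the **differential activity**
   is `DA(m,P) = EG(m,P) / EG(m,control)`.  Modules with DA ≥ 2.5 in a
   phase are selected and assigned to that phase.
3. **Annotation.** Ortholog translation through a static map,
   biomarker-list overlap, and one-sided Fisher (hypergeometric)
   gene-set over-representation with BH adjustment.
4. **Projection.** Modules are intersected with a measured panel; a
   module is *activated* in a condition when more than 20% of its
   measured genes are differentially expressed (padj < 0.05,
   |log2FC| ≥ 1); the *module score* (mean |log2FC| of measured genes)
   is tested for a positive trend on log10 concentration (OLS, α =
   0.05).
5. **Synthetic data.** A generator plants phase-specific modules into
   a bleomycin-style design (7 days × 8 treated + 8 control, 2,000
   genes) and a targeted-panel concentration series (5 compounds ×
   5 concentrations, 3 vs 3 replicates), so the whole pipeline is
   testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole derivation on the
synthetic data (`Rscript analysis/01_simulate.R 1`, then `02`–`07`;
the argument is the seed).  Equivalently, from R:

```r
library(fibromod)
sim <- simulate_invivo(simulation_config(seed = 1))
mods <- detect_modules(sim$expr, network_params())
mods
#> module_set: 8 module(s), 1046 gene(s) assigned, 954 unassigned
#> sizes: 1=247, 2=173, 3=156, 4=126, 5=99, 6=91, 7=90, 8=64
rep <- phase_activity_report(mods, phase_map(sim$design))
rep[1:4, c("module_id", "size", "hub_gene", "DA_inflammatory",
           "DA_acute", "DA_late", "assigned_phases")]
#>  module_id size hub_gene DA_inflamm. DA_acute DA_late assigned_phases
#>          1  247    g0140        4.95     1.75    2.44   inflammatory
#>          2  173    g0736        4.89     8.59    5.87   inflammatory,acute,late
#>          3  156    g0778        2.50     3.45    4.28   acute,late
#>          4  126    g1005        2.41     2.18    3.74   late
```

Eight modules are detected on this seed (planted: eight, sizes
58–250); every module's differential activity peaks in its planted
phase and exceeds the 2.5 selection threshold, so all eight are
selected — the synthetic analogue of the eight-module biomarker set.
Projecting the modules onto the synthetic five-compound panel
(`analysis/06_projection.R`) activates all eight modules at the top
concentration for each fibrosis-inducing compound, none for the inert
solvent, and yields dose-responsive module scores
(slope > 0, p < 0.05) for 24/24 module × fibrotic-compound pairs on
this seed.

The methods vignette (`vignettes/fibromod-methods.Rmd`) documents the
model, every tunable parameter, the generator's design and its
limitations.

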