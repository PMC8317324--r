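---
title: "Screening staged-disease miRNA biomarkers from serum EV counts"
author: "evmirnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening staged-disease miRNA biomarkers from serum EV counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmirnet)
```

## The problem

Serum extracellular vesicles (EVs) protect their miRNA cargo from nucleases,
which makes EV-derived miRNA profiles attractive blood-based biomarkers for
neurodegenerative disease. Given a miRNA-by-sample count matrix from a
cohort of healthy controls and patients at clinical stages II, III and IV,
the screening question is twofold: which miRNAs mark the disease at *every*
stage (diagnostic candidates), and which mark exactly *one* stage
(progression candidates)?

`evmirnet` implements a complete screening pipeline for this design:

1. **Dual differential expression.** Every pairwise group contrast is
   tested twice: with a negative-binomial conditional exact test on counts
   (common dispersion, edgeR-style) and with a Welch *t*-test on logCPM.
   A miRNA is called by the NB route when `P < 0.05` and `|log2FC| > 1`,
   and by the *t* route when `P < 0.05` and `|t| > 2`. The union of both
   routes over all contrasts, minus miRNAs expressed (nonzero) in fewer
   than half of the samples, is the DE set. No multiple-testing correction
   is applied at this step by default — a deliberate fidelity choice to the
   screening design this package reproduces; BH-adjusted calling is
   available via `de_test(adjust = TRUE)`.
2. **Per-stage weighted co-expression networks.** On sample subsets the DE
   set is turned into an unsigned weighted network
   (`a_ij = |cor|^beta`), summarized by the topological overlap matrix
   (TOM), clustered by average linkage on `1 - TOM`, cut into modules with
   a dynamic-hybrid-style procedure (adaptive height cut plus medoid
   adoption of stray leaves), and merged by module-eigengene similarity.
3. **Cross-stage module linkage.** Modules of different stage networks are
   linked by the number of miRNAs they share. Two arms are built: the
   *all-stage arm* (one network per group on the pooled DE set) feeds the
   common-marker call; the *per-stage arm* (one network per disease stage
   on that stage's control-vs-stage DE set) feeds the stage-specific call.
4. **Key-module filtering.** Modules are retained if they are enriched in
   an offline function-set table (one-sided hypergeometric, BH FDR < 0.05
   across the whole module-by-set family; per-stage arm) and contain at
   least one miRNA from an offline disease-annotation table (both arms).
5. **Candidate extraction.** *Common* candidates sit in a retained module
   of every disease stage in the all-stage arm; *specific* candidates sit
   in retained modules of exactly one stage in the per-stage arm.
6. **Validation.** Candidates are scored by ROC/AUC with DeLong 95% CIs
   (common: each stage vs control; specific: own stage vs control and vs
   each other stage) and by qPCR relative quantification
   (`2^-ddCt` against a U6 reference and the control-group mean) with
   one-way ANOVA plus Dunnett many-to-one comparisons. The final reported
   set is the intersection of the ROC-validated and qPCR-validated sets.

## The synthetic cohort generator

The study design this pipeline reproduces did not deposit its sequencing
data, so the package ships a first-class generator
(`simulation_config()` / `generate_cohort()`) that emulates the cohort's
statistical structure with planted ground truth:

* Counts are negative binomial with `Var = mu + phi mu^2` and a single
  dispersion `phi = 0.1`; library sizes are lognormal around one million
  reads (`sdlog = 0.3`).
* `log2 mu = baseline + group effect + loading * module factor +
  log2(libsize/1e6)`. Background baselines span log2CPM −5..15, matching
  the global density of a serum EV miRNA profile; planted module members
  draw from the well-expressed band 2..12, because co-expression of
  near-zero counts is unobservable under any method.
* Co-expression is induced by one latent Gaussian factor per module per
  sample, scaled by `within_module_loading` (default 0.9). A
  stage-specific module's program is active only in that stage's samples;
  the common module's program runs everywhere. This mirrors the biology
  the pipeline assumes: disease-program co-expression exists where the
  program is active.
* One planted module carries the common effect (log2FC 2 in every disease
  stage), and one module per stage carries the stage effect (log2FC 2 in
  its stage only). Effects alternate in sign along each module, so planted
  markers include both up- and down-regulated species. *All* members of a
  planted module carry its effect — a single DE miRNA could never form a
  co-expression module — and the named markers are the module members the
  annotation fixture covers, emulating partial curation of a disease
  database.
* The desk-scale default is 300 miRNAs over 60 samples (15/10/20/15 for
  control/II/III/IV); `profile = "fullsize"` switches to the study scale
  of 1486 miRNAs over 103 samples (31/8/42/22).

Fixture generators accompany the cohort: `generate_annotation_fixture()`
(planted markers with optional dropout, plus decoys) emulates an offline
disease-annotation table; `generate_function_sets()` (module-biased and
uniform sets) emulates an offline miRNA function-set resource;
`generate_ct_table()` produces qPCR Ct values from the closed form
`Ct = intercept − slope·log2(1 + CPM) + noise` with a constant-mean U6
reference row, so that noise-free tables round-trip exactly through
`ddct_fold_change()`.

What the generator does *not* emulate: isoform/isomiR structure, sequence-
driven biases, batch effects, correlated library composition, or any
relation between annotation fixtures and real disease databases. Passing
tests therefore demonstrate that the pipeline recovers the structure it
assumes, at these sample sizes and effect sizes — not that it would
recover biology from an arbitrary real cohort.

## Numerical and design choices

**NB exact test.** Unequal effective libraries (TMM × library size) are
handled by scaling counts to the geometric-mean effective library and
rounding the group sums; the conditional two-sided p-value sums
probabilities of splits no more likely than the observed one, over the
support region carrying all but ~1e-12 of the conditional mass. The common
dispersion is a profile maximum-likelihood estimate with per-group moment
means. As `phi → 0` the test converges to the binomial exact test, and a
2000-miRNA null simulation rejects at 3–7% at `P < 0.05` (both are
asserted in the test suite).

**Soft-threshold power.** `pick_soft_threshold()` implements scale-free
selection (smallest power whose binned log-log connectivity fit reaches
r² = 0.8 with negative slope, else the best-fitting power). On the small
screened gene sets this pipeline produces (50–130 nodes), the fit index is
non-identifying — it can increase with the power as the network
disconnects — so the pipeline default is the fixed canonical unsigned
power `beta = 6`, with `beta = "auto"` available. Printed per-stage values
0.05/0.43/0.05/0.05 from the reproduced design are treated as TOM
edge-*export* thresholds (`tom_export_thresholds`), not powers: a
soft-threshold power below 1 would contradict its own convention.

**Module detection.** The dendrogram cut height adapts to network density:
`1 − m·mean(off-diagonal TOM)` with `m` set by `deepSplit` (2 by default,
m = 2). A fixed fraction of the dendrogram top (the common alternative)
lumps chance joins into module cores on noisy 10–20-sample networks.
Cores need `min_module_size = 5` leaves (miRNA-scale networks are small);
stray leaves are adopted by the module whose medoid they most resemble
when that similarity reaches 10% of the module's own member-to-medoid
similarity, else they stay `grey`. Module merging uses eigengene
dissimilarity `1 − |cor|` with threshold 0.25 (`|cor| > 0.75` merges); the
absolute value keeps the dissimilarity in `[0, 1]`, consistent with the
unsigned network, and makes the threshold-1 limit collapse all correlated
modules.

**Arm construction.** Per-stage networks use the stage's own samples
(`stage_network_samples = "stage_only"`). Including the control samples
folds the case-control axis into the correlation structure: all
disease-responsive genes then co-vary through the group indicator and
module identity blurs, which dilutes function-set enrichment. The
`"stage_plus_control"` mode is available for the alternative reading.

**Candidate classes.** When a miRNA qualifies as both common and specific,
the specific call wins and the common set is reduced: stage-specificity is
demonstrated in the stage-resolved arm, whereas pan-stage membership can
arise from weak chance module assignments in 10–20-sample group networks.
True common-module genes appear in all three per-stage networks and so can
never be claimed specific.

**qPCR statistics.** Dunnett-adjusted comparisons are computed on the
log2-fold (−ddCt) scale by default (`qpcr_scale = "log2_fold"`): raw
`2^-ddCt` ratios are lognormal and heteroscedastic, violating the ANOVA
assumptions at the group sizes in play. The raw-fold mode mirrors the
common plot-scale practice and remains available. The Dunnett tail
probability is evaluated by deterministic two-level quadrature over the
one-factor representation of the equicorrelated multivariate-t — exact for
any number of comparisons, cross-checked against `multcomp`.

**Validation calls.** A candidate is ROC-validated when every required
contrast's DeLong CI excludes 0.5; qPCR-validated when the Dunnett pattern
matches its class (common: `p < 0.05` in all three stages; specific:
`p < 0.05` in its own stage only).

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(seed = 1, simulation = simulation_config(seed = 1))
res <- run_pipeline(cfg)
print(res)
res$candidates$table          # candidate miRNAs with class and stage
res$validation$roc            # per-contrast AUC, CI, p
res$summary$both_validated    # the final reported set
```

Problem sizes used throughout the documentation and tests are the
desk-scale defaults (300 × 60; per-network gene sets of 50–130); the
`fullsize` profile reproduces the study scale and runs the same code
unchanged.

## Known limitations

* The conditional exact test assumes a common dispersion; tagwise or
  trended shrinkage is out of scope, and the geometric-mean library
  equalization is an approximation (calibration is verified by
  simulation, not theory).
* Module detection on 8–15-sample networks is intrinsically fragile;
  weakly expressed module members can drop to `grey` in one stage network
  and chance adoption cannot be fully excluded. The candidate-class
  precedence above absorbs most, not all, of this noise.
* Enrichment uses the screened DE set as background (conditional on the
  screen); results are not comparable to whole-miRNome enrichment.
* The ROC p-value is the DeLong normal approximation; with very small
  groups and perfect separation it degenerates to 0, and the CI is
  clipped to `[0, 1]`.
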