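---
title: "Methods: mixture-model gating and compositional inference for multiplex IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture-model gating and compositional inference for multiplex IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexcompo)
```

## The problem

Multiplex immunohistochemistry (mIHC) on tyramide-amplified Opal panels
yields, after segmentation, a table with one row per cell and one mean
fluorescence intensity per marker. Turning that table into biology
requires three steps that this package implements end to end:

1. **Gating** — decide, per marker, which cells are positive;
2. **Phenotyping and composition** — combine marker calls into mutually
   exclusive cell types and tabulate their percentages per sample and
   tissue compartment (dermis/epidermis);
3. **Compositional inference** — test whether groups of samples (here,
   clinical subtypes of lichen planus and non-diseased control skin)
   differ in composition, and which cell types drive the difference.

A seeded synthetic-cohort generator with full ground truth accompanies
the pipeline, so every stage is testable without patient data. A
simplified differential-expression screen for targeted count panels
(housekeeping normalization, Welch tests on log2 counts,
Benjamini–Hochberg adjustment, fold-change/FDR cut-offs) rounds out the
toolkit.

## Marker gating by two-component mixtures

For one marker in one fitting unit (a sample, or the pooled cohort),
intensities are modelled as a two-component finite mixture

$$f(x) = w^- f^-(x) + w^+ f^+(x),$$

where both components belong to one family — normal, log-normal or
Weibull — and the **positive component is the one with the larger
distribution mean** (not the larger mode; for skewed families these can
disagree). Fitting is by EM:

* the normal M-step is the weighted mean/variance update;
* the log-normal fit runs the normal EM on log intensities, with the
  log-likelihood reported on the original scale (Jacobian included) so
  that families are comparable;
* the Weibull M-step profiles the shape with a warm-started
  one-dimensional root solve and gets the scale in closed form.

EM stops when the log-likelihood improves by less than `tol` (default
1e-8) or after `max_iter = 500` iterations; the best of three seeded
initializations by log-likelihood wins. The first initialization is a
k-means split; the second cuts at the 95th percentile — essential for
rare positive populations (well below 5 % of cells), where k-means
splits the background bulk instead; the third cuts at a random
quantile. Restarts whose components collapse (vanishing scale or
weight) are discarded; if all collapse the fit carries
`status = "failed"`.

**Family choice** is by BIC across the candidate families (5 free
parameters each), ties broken in the fixed order normal < lognormal <
weibull. A cell's posterior probability of positivity is the Bayes
ratio $w^+ f^+(x) / (w^- f^-(x) + w^+ f^+(x))$, computed with log
densities; a cell is called positive when this posterior **strictly
exceeds 0.95** (a posterior of exactly 0.95 is negative). Intensities
below the support of the family (e.g. $x \le 0$ for a log-normal) get
posterior 0: signal cannot sit below the support floor.

Two safeguards matter in practice:

* **When is the asinh transform applied?** `asinh(x / cofactor)`
  (cofactor default 1) is a standard variance-stabilizer, but
  transforming and then fitting a generic family to data that is
  already log-normal is a misspecification that audibly degrades
  posterior calibration near the 0.95 gate (we measured ~40 % of a
  17 %-positive population lost on a draft that transformed whenever
  skewness exceeded 2). The pipeline therefore prefers the raw scale
  whenever a right-skew-capable family (log-normal or Weibull) can be
  fitted directly, and reaches for asinh only when the histogram is
  skewed (|skewness| > 2) with no such family available — e.g.
  normal-family-only gating, or intensities containing zeros or
  negatives — or when every raw fit fails.
* **Markers with no positive population.** On a slide where a marker
  stains nothing, the intensity histogram is unimodal; a forced
  two-component fit will split the background and, untreated, call
  half the tissue positive. Fits whose components are separated by
  fewer than 2 pooled standard deviations are flagged
  `low_separation`, and `gate_cells()` calls every cell negative for
  that marker in that unit.

Gating is per sample by default (`mode = "per_sample"`), which absorbs
slide-to-slide staining variation; `mode = "pooled"` fits one model per
marker across the cohort and is preferable when per-sample positive
populations are too small to estimate (it is also ~n-fold faster). With
more than `max_fit_cells` (25 000) cells in a unit the model is fitted
on a seeded subsample — far beyond the size needed for stable
two-component estimates — and posteriors are computed for all cells.

## Phenotypes and panel structure

Composite phenotypes come from ordered rules per panel. The T-cell
panel (CD8, FoxP3, IL17A, GranzymeB, PanCK, CD4) uses the priority

Treg (FoxP3+) → IL17A+ → GranzymeB+ → CD8+ T → CD4+ T →
keratinocyte (PanCK+) → other,

so that a FoxP3+ CD4+ cell is a Treg and categories are mutually
exclusive and exhaustive. Whether a Treg should require CD4
co-positivity is a genuinely open design point; the default is
FoxP3-only, switchable with `tcell_panel(treg_requires_cd4 = TRUE)`.
The macrophage panel (pSTAT1, MPO, cMaf, PanCK, CD68) assigns
M1 (CD68+ pSTAT1+) and M2 (CD68+ cMaf+) in one priority tier — a cell
positive for both polarization markers goes to the one with the higher
posterior — then plain macrophage (CD68+), neutrophil (MPO+),
keratinocyte, other. All-negative cells are always `"other"`.

Compositions are percentages of all cells in a stratum (sample ×
compartment); pooling by subtype is **cell-weighted** (all cells
concatenated before counting), not a mean of per-sample percentages.
`derive_totals()` adds the derived rows used in reporting: Total T
cells = CD4+ T + CD8+ T + Treg + GranzymeB+ + IL17A+, and Total
macrophages = CD68+ + M1 + M2; M1/M2 are reported as sub-fractions and
do not enter the sum-to-100 category set.

**Merging two panels.** Serial sections stained with different panels
each resolve a subset of cell types. The merge takes the T lineages
from the T-cell panel, macrophage/neutrophil categories from the
macrophage panel, averages the shared categories (keratinocyte,
"other") with cell-count weights, and renormalizes to 100. One
correction is essential: each panel's "other" also contains the cell
types only the opposite panel can see, so the opposite panel's
exclusive-category mass is subtracted from each "other" before
averaging. Without it, "other" is double-inflated and renormalization
biases every lineage low by 15–25 % relative; with it, merged
compositions recover a shared simulated truth to within one percentage
point. How the original two-panel data became one composition table is
not documented anywhere we could find; this rule is our own
reconstruction and is flagged as such.

## Compositional inference

All test statistics are implemented from first principles (vegan serves
as an independent cross-check in the test suite, never as the
implementation):

* **Bray–Curtis dissimilarity** $\sum_i |a_i - b_i| / \sum_i (a_i + b_i)$
  on percentage compositions.
* **NMDS**: Kruskal stress-1 minimization. Each iteration fits a
  monotone (pool-adjacent-violators) regression of configuration
  distances on the dissimilarity order — ties handled by the primary
  approach (tied dissimilarities impose no mutual constraint) — then
  moves the configuration by a Guttman transform with step-halving, so
  stress is non-increasing within a run. Restart 1 starts from
  classical metric scaling; 19 further restarts add seeded jitter. A
  Euclidean-embeddable input reaches stress below 1e-10.
* **PERMANOVA**: pseudo-F from the distance-based partition
  $SS_{total} = \frac{1}{n}\sum_{i<j} d_{ij}^2$,
  $SS_W = \sum_g \frac{1}{n_g} \sum_{i<j \in g} d_{ij}^2$,
  $F = \frac{SS_A/(g-1)}{SS_W/(n-g)}$, with a seeded label-permutation
  null and the add-one correction
  $p = (\#\{F_\pi \ge F_{obs}\} + 1)/(n_{perm}+1)$, so $p \ge
  1/(n_{perm}+1)$ and is never zero. The default is 9 999
  permutations. Pairwise contrasts restrict the matrix to each pair
  and report **raw** p-values (no multiplicity adjustment). Groups of
  size one are rejected — they have no within-group distances.
* **SIMPER**: the mean between-group Bray–Curtis decomposes exactly
  into per-category contributions (mean over cross-group pairs of
  $|x_{ai}-x_{bi}| / \sum_k (x_{ak}+x_{bk})$); contributions sum to the
  mean dissimilarity to 1e-10 by construction, and each category's
  permutation p-value measures the consistency of its contribution
  across samples. Percentages are reported as percent of **total**
  dissimilarity (not of an "explained" subset).
* **CLR-ANOVA**: per-category one-way fixed-effects ANOVA after the
  centred log-ratio transform. Zeros are handled by multiplicative
  replacement with $\delta$ = half the smallest nonzero proportion in
  the matrix — a single shared $\delta$ so all samples live in the same
  simplex. A category with zero residual variance but distinct group
  means is reported with $F = \infty$, $p = 0$, and flagged.
* **Fisher's exact test**: 2×2 tables exactly, by hypergeometric
  enumeration with the point-probability two-sided rule; larger tables
  by seeded Monte Carlo over fixed-margin tables (default 1e5 draws,
  add-one corrected). The exact network algorithm for r×c tables is
  out of scope.

## The synthetic cohort

`simulate_cell_table()` emulates what the upstream segmentation
exports. Its defaults are the package's study conditions:

* **Composition targets** are the published pooled percentages of the
  five lichen planus study groups (classical, genital, oral, lichen
  planopilaris, non-diseased control), shipped as `lp_cell_percentages()`.
* **Inter-sample variability** is Dirichlet around the group target
  with concentration 200. The source data report only pooled
  percentages, so sample-level scatter is our choice: concentration
  200 gives a standard deviation of ±3 percentage points on a
  30 %-category — the scatter of biological replicates — without
  degenerate zeros.
* **Intensities**: both components log-normal by default (the typical
  shape of fluorescence intensities); normal and Weibull families are
  available to exercise all three fit families. Defaults are
  background mean 1 (sd 0.6) and signal mean 15 (sd 4) in arbitrary
  units: a bright, well-titrated tyramide-amplified stain at ~15×
  background (~6.5 pooled log-scale SDs), the regime where a strict
  0.95-posterior gate loses almost no true positives. Dim assays (≤8×
  background) are simulated by lowering `pos_mean`; there the strict
  gate's conservatism becomes visible as boundary positives called
  negative.
* **Compartments**: keratinocytes are epidermal with probability 0.8,
  all other types with probability 0.2 (configurable). Real per-sample
  cell counts are not reported anywhere; the default of a few thousand
  cells per sample is an invented, documented choice.
* Per-cell truth (phenotype, marker positivity) and per-sample truth
  (the Dirichlet draw) are returned alongside the table; seeds are
  explicit arguments and never touch global RNG state.
* `simulate_two_panel_cohort()` draws one composition per sample over
  the union category set and generates an independent cell table per
  panel from that shared truth — serial sections of one block.

What the generator deliberately does **not** emulate: spatial
structure, autofluorescence and spectral bleed-through, segmentation
errors (doublets, partial cells), batch effects between slides, and
marker co-expression beyond the phenotype rules. Passing tests
therefore certify the statistical pipeline under a clean generative
model, not robustness to imaging artefacts.

`simulate_count_matrix()` generates the DE screen's input: negative
binomial counts (log-normal baseline means across genes), housekeeping
genes pinned to zero fold change, planted log2 fold changes applied to
the non-reference groups.

## The differential-expression screen

The screen is an explicitly simplified stand-in for proprietary panel
software: per-sample scale factors from housekeeping geometric means
(cohort geometric mean / sample geometric mean; +0.5 pseudocount if a
housekeeping count is zero), Welch's unequal-variance t-test on
$\log_2(x+1)$, Benjamini–Hochberg adjustment, and significance at
|fold change| ≥ 1.5 **and** adjusted p ≤ 0.05 (the α comparison
inclusive, the fold-change strict at the printed 1.5). Linear fold
changes below one are reported as negative reciprocals. The underlying
"fast method" of the commercial stack is not publicly specified; Welch
on log2 counts is our documented choice and is isolated behind
`de_test()` so it can be swapped. Background subtraction from
negative-control probes and gene-set scoring are out of scope.

## Problem sizes used in the checks

The shipped tests and the acceptance script exercise: the published
table aggregation (five columns); 100 six-sample PERMANOVA instances
against full enumeration (9 999 permutations each); 500 null datasets
for type-I calibration (999 permutations, 10 samples); 1 000 random
SIMPER instances for the decomposition identity; 3 000-cell markers
for gating recovery; a 10-point planar NMDS recovery; 1 000 random
p-vectors for the BH oracle; and a full two-panel cohort of 5 subtypes
× 5 samples × 2 000 cells per panel for the end-to-end composition
recovery and pairwise PERMANOVA. These sizes give stable Monte-Carlo
behaviour while keeping a complete run in minutes on one core.

## Known limitations

* Gating assumes exactly two components; partially stained or
  trimodal markers are not modelled (`k > 2` is out of scope).
* The merge of two panels assumes serial sections share a composition;
  physically distant sections violate this.
* Percentage compositions ignore absolute cell density (cells/mm²),
  which the source data do not report.
* Permutation p-values are bounded below by 1/(n_perm+1); with 5
  samples per group, pairwise PERMANOVA cannot go below ~1/252 in
  distinct partitions.
* The DE screen's Welch-on-log2 model is a stand-in; its fold changes
  are not comparable to vendor-pipeline output on real data.
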