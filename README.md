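# plexcompo

Cell phenotyping and compositional statistics for multiplex
immunohistochemistry (mIHC).

Segmentation software for multiplexed immunofluorescence panels (e.g.
Opal/Vectra) exports a table with one row per cell and one mean
intensity per marker. `plexcompo` turns that table into population
biology for cohort studies — here parameterized for lichen planus (LP)
skin subtypes versus non-diseased control skin — and is aimed at
analysts who want every step of that pipeline scriptable, seeded and
testable:

1. **Marker gating.** Per marker, intensities are modelled as a
   two-component finite mixture `w⁻f⁻(x) + w⁺f⁺(x)` (normal,
   log-normal or Weibull components; chosen by BIC; fitted by EM).
   A cell is called positive when its posterior probability of the
   positive (higher-mean) component strictly exceeds 0.95:
   `P(+|x) = w⁺f⁺(x) / (w⁻f⁻(x) + w⁺f⁺(x))`.
2. **Phenotyping.** Ordered panel rules combine calls into mutually
   exclusive phenotypes (e.g. Treg = FoxP3+, M1 = CD68+ pSTAT1+);
   all-negative cells are `"other"`.
3. **Composition.** Per-sample and cell-weighted pooled percentages by
   tissue compartment, with derived totals (Total T cells, Total
   macrophages) and a documented rule for merging two antibody panels
   stained on serial sections.
4. **Inference.** Bray–Curtis dissimilarity `Σ|aᵢ−bᵢ|/Σ(aᵢ+bᵢ)`, NMDS
   (Kruskal stress-1 with isotonic regression), PERMANOVA
   (pseudo-F = (SS_A/(g−1))/(SS_W/(n−g)) with a seeded permutation
   null), pairwise PERMANOVA, SIMPER decomposition of between-group
   dissimilarity, CLR-transform ANOVA, and exact/Monte-Carlo Fisher
   tests — all implemented from first principles and cross-checked
   against vegan in the test suite.
5. **DE screen.** A deliberately simple differential-expression screen
   for targeted count panels: housekeeping geometric-mean
   normalization, Welch t on log2(x+1), Benjamini–Hochberg, and
   significance at |fold change| ≥ 1.5 and adjusted p ≤ 0.05.

A synthetic-cohort generator with complete ground truth (per-cell
phenotypes, per-sample Dirichlet compositions, planted fold changes)
ships as first-class, tested code, parameterized by the published
pooled cell-type percentages of five study groups (`lp_cell_percentages()`).

## Worked example

Simulate a small two-group cohort, gate it, and test the composition:

```r
library(plexcompo)

cfg <- cohort_config(c("classical", "NDC"), samples_per_subtype = 3,
                     cells_per_sample = 1000, seed = 1)
sim   <- simulate_cell_table(cfg)
gated <- gate_cells(sim$cells, cfg$panel, mode = "pooled", seed = 1)
comp  <- composition(gated)
dplyr::filter(comp, cell_type == "Treg")
#>   sample_id    subtype   compartment cell_type     n n_cells percent
#> 1 classical_s1 classical all         Treg        293    1000    29.3
#> 2 classical_s2 classical all         Treg        211    1000    21.1
#> 3 classical_s3 classical all         Treg        240    1000    24
#> 4 NDC_s1       NDC       all         Treg         15    1000     1.5
#> 5 NDC_s2       NDC       all         Treg         24    1000     2.4
#> 6 NDC_s3       NDC       all         Treg         26    1000     2.6
```

Tregs are ~20–30 % of cells in the classical-LP samples and ~2 % in
control skin, as the generator's published targets dictate. Pool by
group and derive the reporting totals:

```r
pooled <- pool_compositions(gated)
derive_totals(pooled) |> dplyr::filter(cell_type == "Total T cells")
#>   subtype   compartment cell_type         n n_cells percent
#> 1 NDC       all         Total T cells    79    3000    2.63
#> 2 classical all         Total T cells  1314    3000   43.8
```

Distance-based inference on the per-sample compositions:

```r
d  <- bc_distance_matrix(comp)
permanova(d, rep(c("classical", "NDC"), each = 3), n_perm = 9999, seed = 1)
#> <plex_permtest> permanova: statistic = 76.244, p = 0.094
#>                 (9999 permutations, seed 1)
```

The pseudo-F is enormous, but with 3 samples per group only 20 distinct
label partitions exist, so the permutation p cannot go below ~0.1 —
the test is honest about tiny designs. Which cell types drive the
dissimilarity:

```r
simper(comp, "classical", "NDC", n_perm = 999, seed = 1) |> head(3)
#>   cell_type    contribution percent p_value
#> 1 keratinocyte       0.176    42.5    0.06
#> 2 Treg               0.113    27.4    0.046
#> 3 CD4+ T             0.0353   8.56    0.065
```

Keratinocyte dilution and Treg infiltration carry ~70 % of the
between-group Bray–Curtis distance, and the per-category p-values
report how consistently samples contribute. `nmds(d)` embeds the
samples for plotting (`autoplot()`), and `clr_anova()`/`fisher_exact()`
cover the per-category and pooled-count tests.

## Documentation

The methods vignette (`vignettes/plexcompo-methods.Rmd`) describes the
mixture model and its safeguards, the phenotype priority rules, every
statistic's exact formula and permutation scheme, what the synthetic
cohort does and does not emulate, and the package's known limitations.
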