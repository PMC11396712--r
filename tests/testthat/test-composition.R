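test_that("composition is a direct percentage of stratum counts", {
  cells <- toy_cells(c(Treg = 3, other = 7))
  comp <- composition(cells)
  expect_equal(comp$percent[comp$cell_type == "Treg"], 30)
  expect_equal(comp$percent[comp$cell_type == "other"], 70)
  expect_equal(sum(comp$percent), 100)

  mono <- composition(toy_cells(c(keratinocyte = 12)))
  expect_equal(
    mono$percent[mono$cell_type == "keratinocyte"], 100
  )
  # "other" is always carried as a category
  expect_true("other" %in% mono$cell_type)
})

test_that("compartment filtering drops empty strata with a warning", {
  cells <- dplyr::bind_rows(
    toy_cells(c(Treg = 5), sample_id = "s1", compartment = "dermis"),
    toy_cells(c(Treg = 5), sample_id = "s2", compartment = "epidermis")
  )
  expect_warning(
    comp <- composition(cells, compartment = "dermis"),
    "omitted: s2"
  )
  expect_equal(unique(comp$sample_id), "s1")
})

test_that("composition equals ground truth when gating is bypassed", {
  cfg <- cohort_config(c("classical", "oral"), 2, 400, seed = 3)
  sim <- simulate_cell_table(cfg)
  cells <- sim$cells
  cells$phenotype <- sim$truth$cells$true_type
  comp <- composition(cells)
  truth_counts <- table(
    sim$truth$cells$sample_id, sim$truth$cells$true_type
  )
  for (i in seq_len(nrow(comp))) {
    expect_equal(
      comp$percent[i],
      100 * truth_counts[comp$sample_id[i], comp$cell_type[i]] / 400
    )
  }
})

test_that("pooling is cell-weighted, not a mean of percentages", {
  cells <- dplyr::bind_rows(
    toy_cells(c(Treg = 10, other = 90), sample_id = "s1"),
    toy_cells(c(Treg = 90, other = 210), sample_id = "s2")
  )
  pooled <- pool_compositions(cells, group = "subtype")
  expect_equal(pooled$percent[pooled$cell_type == "Treg"], 25) # not 20
  expect_equal(sum(pooled$percent), 100, tolerance = 0.2)
  # one sample: pooled equals the per-sample composition
  single <- toy_cells(c(Treg = 4, other = 16))
  expect_equal(
    sort(pool_compositions(single, group = "subtype")$percent),
    sort(composition(single)$percent)
  )
})

test_that("pooling by group commutes with composition of combined cells", {
  cfg <- cohort_config("genital", 3, 300, seed = 6)
  sim <- simulate_cell_table(cfg)
  cells <- sim$cells
  cells$phenotype <- sim$truth$cells$true_type
  pooled <- pool_compositions(cells, group = "subtype")
  merged_cells <- cells
  merged_cells$sample_id <- "all"
  direct <- composition(merged_cells)
  m <- merge(
    as.data.frame(pooled[, c("cell_type", "percent")]),
    as.data.frame(direct[, c("cell_type", "percent")]),
    by = "cell_type"
  )
  expect_equal(m$percent.x, m$percent.y)
})

test_that("published T-lineage percentages sum to the printed totals", {
  tab <- lp_cell_percentages(include_totals = FALSE)
  printed <- lp_cell_percentages(include_totals = TRUE)
  tot <- derive_totals(tab)
  for (s in unique(tab$subtype)) {
    derived <- tot$percent[
      tot$subtype == s & tot$cell_type == "Total T cells"
    ]
    shown <- printed$percent[
      printed$subtype == s & printed$cell_type == "Total T cells"
    ]
    expect_lt(abs(derived - shown), 0.1)
    # macrophage sub-fractions reassemble the printed total
    dmac <- tot$percent[
      tot$subtype == s & tot$cell_type == "Total macrophages"
    ]
    smac <- printed$percent[
      printed$subtype == s & printed$cell_type == "Total macrophages"
    ]
    expect_lt(abs(dmac - smac), 1e-9)
  }
})

test_that("totals derivation handles edge cases", {
  zero <- tibble::tibble(
    subtype = "z",
    cell_type = c(
      "CD4+ T", "CD8+ T", "Treg", "GranzymeB+", "IL17A+", "other"
    ),
    percent = c(0, 0, 0, 0, 0, 100)
  )
  tot <- derive_totals(zero)
  expect_equal(
    tot$percent[tot$cell_type == "Total T cells"], 0
  )
  expect_error(
    derive_totals(zero[zero$cell_type != "Treg", ]),
    "Treg"
  )
})

test_that("panel merge preserves shared categories and renormalizes", {
  strat <- function(ct, pc, n) {
    tibble::tibble(
      sample_id = "s1", compartment = "all", cell_type = ct,
      percent = pc, n_cells = n
    )
  }
  comp_t <- strat(
    c("Treg", "CD8+ T", "CD4+ T", "GranzymeB+", "IL17A+",
      "keratinocyte", "other"),
    c(30, 5, 5, 1, 2, 25, 32), 1000
  )
  comp_m <- strat(
    c("macrophage", "M1", "M2", "neutrophil", "keratinocyte", "other"),
    c(9, 1, 1, 1, 25, 63), 1000
  )
  merged <- merge_panels(comp_t, comp_m)
  expect_equal(sum(merged$percent), 100, tolerance = 1e-9)
  # consistent serial sections: identical keratinocyte percentage
  # passes through the merge unchanged
  expect_equal(
    merged$percent[merged$cell_type == "keratinocyte"], 25,
    tolerance = 0.5
  )
  # macrophage-free second panel: result proportional to panel 1
  comp_m0 <- strat(
    c("macrophage", "M1", "M2", "neutrophil", "keratinocyte", "other"),
    c(0, 0, 0, 0, 25, 75), 1000
  )
  merged0 <- merge_panels(comp_t, comp_m0)
  t_only <- merged0$percent[match(comp_t$cell_type, merged0$cell_type)]
  expect_equal(t_only / sum(t_only), comp_t$percent / sum(comp_t$percent),
    tolerance = 0.02
  )
  # a lineage claimed by both panels is an error
  clash <- comp_m
  clash$cell_type[1] <- "Treg"
  expect_error(merge_panels(comp_t, clash), "claimed by both")
})

test_that("merging two simulated panels recovers the shared truth", {
  tp <- simulate_two_panel_cohort(c("classical", "planopilaris"), 3, 2500,
    seed = 21
  )
  ct <- tp$tcell$cells
  ct$phenotype <- tp$tcell$truth$cells$true_type
  cm <- tp$macrophage$cells
  cm$phenotype <- tp$macrophage$truth$cells$true_type
  merged <- merge_panels(pool_compositions(ct), pool_compositions(cm))
  truth <- tp$truth_composition |>
    dplyr::group_by(.data$subtype, .data$cell_type) |>
    dplyr::summarise(percent = 100 * mean(.data$proportion), .groups = "drop")
  m <- merge(
    as.data.frame(merged[, c("subtype", "cell_type", "percent")]),
    as.data.frame(truth),
    by = c("subtype", "cell_type")
  )
  expect_lt(max(abs(m$percent.x - m$percent.y)), 1)
})
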