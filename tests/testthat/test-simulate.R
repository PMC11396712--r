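test_that("same seed reproduces a byte-identical cell table", {
  cfg <- cohort_config(c("classical", "NDC"), 2, 200, seed = 7)
  a <- simulate_cell_table(cfg)
  b <- simulate_cell_table(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth, b$truth)
  fa <- withr::local_tempfile(fileext = ".tsv")
  fb <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(a$cells, fa)
  write_cell_table(b$cells, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
    readBin(fb, "raw", file.size(fb))
  )
})

test_that("generator leaves the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  simulate_cell_table(cohort_config("classical", 1, 60, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("degenerate Dirichlet pins every sample to the group target", {
  cfg <- cohort_config(c("classical", "oral"), 3, 100,
    dirichlet_concentration = Inf, seed = 2
  )
  sim <- simulate_cell_table(cfg)
  for (g in cfg$subtypes) {
    target <- cfg$composition_targets[[g]]
    comp <- sim$truth$composition[sim$truth$composition$subtype == g, ]
    for (sid in unique(comp$sample_id)) {
      d <- comp[comp$sample_id == sid, ]
      expect_equal(stats::setNames(d$proportion, d$cell_type)[names(target)],
        target,
        tolerance = 1e-12
      )
    }
  }
})

test_that("drawn per-sample compositions sum to one", {
  cfg <- cohort_config(c("classical", "genital", "NDC"), 4, 50, seed = 9)
  sim <- simulate_cell_table(cfg)
  sums <- tapply(
    sim$truth$composition$proportion, sim$truth$composition$sample_id, sum
  )
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("empirical Treg fraction hits the published classical target", {
  # classical target: Tregs 30.3% of all cells (before renormalization)
  cfg <- cohort_config("classical", 5, 2000, seed = 1)
  sim <- simulate_cell_table(cfg)
  frac <- tapply(
    sim$truth$cells$true_type == "Treg", sim$truth$cells$sample_id, mean
  )
  # sampling-error bound from the known generative variance:
  # Dirichlet (concentration 200) plus multinomial at 2000 cells
  se <- sqrt(0.303 * (1 - 0.303) * (1 / 201 + 1 / 2000) / 5)
  expect_lt(abs(mean(frac) - 0.303), 3 * se)
})

test_that("true marker-positive intensities converge to the model mean", {
  cfg <- cohort_config("classical", 1, 50000,
    composition_targets = list(
      classical = c(Treg = 0.5, other = 0.5)
    ),
    seed = 4
  )
  sim <- simulate_cell_table(cfg)
  pos <- sim$truth$cells$FoxP3
  m <- mean(sim$cells$FoxP3[pos])
  expect_lt(abs(m - 15) / 15, 0.02)
  m_neg <- mean(sim$cells$FoxP3[!pos])
  expect_lt(abs(m_neg - 1), 0.02)
})

test_that("keratinocytes are enriched in the epidermis", {
  cfg <- cohort_config("planopilaris", 2, 4000, seed = 11)
  sim <- simulate_cell_table(cfg)
  ker <- sim$truth$cells$true_type == "keratinocyte"
  epi <- sim$cells$compartment == "epidermis"
  expect_gt(mean(epi[ker]), 0.75)
  expect_lt(mean(epi[!ker]), 0.25)
})

test_that("invalid configurations are rejected with clear errors", {
  expect_error(
    cohort_config("classical", 1, 10,
      composition_targets = list(classical = c(Treg = 0.6, other = 0.5))
    ),
    "sum to 1"
  )
  expect_error(
    cohort_config("classical", 1, 10,
      composition_targets = list(classical = c(astro = 0.5, other = 0.5))
    ),
    "absent from the panel"
  )
  mm <- default_marker_models(tcell_panel()$markers)
  mm$CD8$family <- "gamma"
  expect_error(
    cohort_config("classical", 1, 10, marker_models = mm),
    "unknown family"
  )
  mm <- default_marker_models(tcell_panel()$markers)
  mm$CD8$pos_mean <- 0.5
  expect_error(
    cohort_config("classical", 1, 10, marker_models = mm),
    "pos_mean"
  )
})

test_that("count matrix simulation is seeded and respects housekeeping", {
  a <- simulate_count_matrix(50, 5, rep(c("g1", "g2"), each = 4), seed = 3)
  b <- simulate_count_matrix(50, 5, rep(c("g1", "g2"), each = 4), seed = 3)
  expect_identical(a$counts, b$counts)
  expect_equal(sum(a$counts$housekeeping), 5)
  expect_true(all(a$truth$log2fc[a$counts$housekeeping] == 0))
  expect_error(
    simulate_count_matrix(50, 5, rep(c("g1", "g2"), each = 4),
      planted_log2fc = c(HK01 = 2)
    ),
    "housekeeping"
  )
})

test_that("two-panel cohorts share one per-sample truth", {
  tp <- simulate_two_panel_cohort(c("classical", "NDC"), 2, 150, seed = 5)
  expect_setequal(names(tp), c("tcell", "macrophage", "truth_composition"))
  # both panels' per-sample truths are folds of the shared draw
  draw <- tp$truth_composition
  tc <- tp$tcell$truth$composition
  s1 <- draw[draw$sample_id == "classical_s1", ]
  t1 <- tc[tc$sample_id == "classical_s1", ]
  full <- stats::setNames(s1$proportion, s1$cell_type)
  folded <- fold_targets_onto_panel(full, tcell_panel())
  expect_equal(
    stats::setNames(t1$proportion, t1$cell_type)[names(folded)],
    folded,
    tolerance = 1e-12
  )
})
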