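test_that("housekeeping normalization undoes a global scale shift", {
  sim <- simulate_count_matrix(60, 6, rep(c("a", "b"), each = 3), seed = 2)
  m <- as.matrix(sim$counts[, -(1:2)])
  rownames(m) <- sim$counts$gene
  hk <- sim$counts$housekeeping

  # identical samples: all factors one
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  norm_same <- normalize_counts(same, hk)
  expect_equal(unname(attr(norm_same, "scale_factors")), rep(1, 3))

  # one sample doubled throughout: factor 1/2 restores it
  doubled <- m
  doubled[, 2] <- 2 * m[, 2]
  norm <- normalize_counts(doubled + 1, hk) # +1 avoids zero housekeeping
  f <- attr(norm, "scale_factors")
  expect_equal(unname(f[2] / f[1]), 0.5, tolerance = 0.02)

  # scalar scaling preserves within-sample gene ratios
  ratios_before <- (doubled[1, ] + 1) / (doubled[2, ] + 1)
  ratios_after <- norm[1, ] / norm[2, ]
  expect_equal(unname(ratios_after), unname(ratios_before))

  expect_error(normalize_counts(m, rep(FALSE, nrow(m))), "housekeeping")
})

test_that("zero housekeeping counts trigger the pseudocount path", {
  m <- matrix(c(0, 10, 20, 30, 40, 50), 3,
    dimnames = list(c("HK1", "g1", "g2"), c("s1", "s2"))
  )
  expect_message(
    normalize_counts(m, c(TRUE, FALSE, FALSE)),
    "pseudocount"
  )
})

test_that("identical groups give zero fold change and p near one", {
  m <- withr::with_seed(3, matrix(stats::rnbinom(40 * 8, mu = 200, size = 20), 40))
  rownames(m) <- paste0("g", 1:40)
  colnames(m) <- paste0("s", 1:8)
  dup <- cbind(m[, 1:4], m[, 1:4])
  colnames(dup) <- paste0("s", 1:8)
  res <- de_test(dup, rep(c("A", "B"), each = 4), "A", "B")
  expect_equal(res$log2fc, rep(0, 40))
  expect_equal(res$p, rep(1, 40))
})

test_that("swapping group labels negates log2fc and keeps p", {
  m <- withr::with_seed(4, matrix(stats::rnbinom(30 * 10, mu = 150, size = 10), 30))
  rownames(m) <- paste0("g", 1:30)
  colnames(m) <- paste0("s", 1:10)
  grp <- rep(c("A", "B"), each = 5)
  ab <- de_test(m, grp, "A", "B")
  ba <- de_test(m, grp, "B", "A")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)
})

test_that("a planted two-fold-change gene is estimated within 0.3", {
  sim <- simulate_count_matrix(100, 5, rep(c("ctrl", "case"), each = 10),
    planted_log2fc = c(gene001 = 2), nb_dispersion = 0.05, seed = 42
  )
  res <- de_screen(sim$counts, sim$groups, "case", "ctrl")
  est <- res$log2fc[res$gene == "gene001"]
  expect_lt(abs(est - 2), 0.3)
  expect_true(res$significant[res$gene == "gene001"])
})

test_that("BH adjustment matches the hand step-up and the oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  for (s in 1:50) {
    p <- withr::with_seed(400 + s, stats::runif(1 + s %% 20))
    q <- bh_adjust(p)
    expect_equal(q, bf_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("significance cut-offs are inclusive on alpha, strict on fold", {
  res <- tibble::tibble(
    gene = c("a", "b", "c", "d"),
    log2fc = log2(c(1.49, 2, 1.6, 0.2)),
    fold_change = c(1.49, 2, 1.6, -5),
    p = c(0.001, 0.01, 0.2, 0.001),
    p_adj = c(0.01, 0.05, 0.3, 0.04)
  )
  sig <- threshold_de(res)
  expect_setequal(sig$gene, c("b", "d")) # 1.49 fails fc; 0.05 passes alpha
  empty <- threshold_de(res[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the screen controls false discoveries under a global null", {
  fracs <- vapply(1:15, function(s) {
    sim <- simulate_count_matrix(150, 8, rep(c("a", "b"), each = 5),
      nb_dispersion = 0.1, seed = 1000 + s
    )
    res <- de_screen(sim$counts, sim$groups, "a", "b")
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("column clustering is deterministic and groups duplicates", {
  m <- withr::with_seed(9, matrix(stats::rnorm(40), 10, 4))
  m <- cbind(m, m[, 2]) # duplicate of column 2
  colnames(m) <- c("c1", "c2", "c3", "c4", "c2dup")
  o1 <- hcluster_order(m)
  o2 <- hcluster_order(m)
  expect_identical(o1, o2)
  expect_equal(abs(diff(match(c("c2", "c2dup"), o1))), 1) # merge first
  # three-column hand case: distances via 1 - Pearson
  m3 <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 2.9, 4.2), c = c(4, 3, 2, 1))
  o3 <- hcluster_order(m3)
  expect_equal(abs(diff(match(c("a", "b"), o3))), 1)
  # constant column: correlation undefined -> distance 1 convention
  m4 <- cbind(m3, k = rep(5, 4))
  expect_equal(length(hcluster_order(m4)), 4)
  expect_error(hcluster_order(m3[, 1, drop = FALSE]), "at least 2")
})
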