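de_matrix <- function(counts) {
  if (is.matrix(counts)) {
    return(list(m = counts, hk = NULL))
  }
  stopifnot(is.data.frame(counts), "gene" %in% names(counts))
  hk <- if ("housekeeping" %in% names(counts)) counts$housekeeping
  num <- setdiff(names(counts), c("gene", "housekeeping"))
  m <- as.matrix(counts[, num, drop = FALSE])
  rownames(m) <- counts$gene
  list(m = m, hk = hk)
}

#' Housekeeping-gene normalization of a count matrix
#'
#' Scales each sample by
#' `(cohort geometric mean of housekeeping counts) /
#' (sample geometric mean of housekeeping counts)`, so samples with
#' globally inflated counts are shrunk back to the cohort level — a
#' deliberately simple content normalization for targeted panels.
#' Housekeeping genes with a zero count in any sample get a +0.5
#' pseudocount for the factor computation (with a message).
#'
#' @param counts Tibble with `gene`, logical `housekeeping` and one
#'   numeric column per sample, or a genes-by-samples matrix (then
#'   supply `housekeeping`).
#' @param housekeeping Logical vector flagging housekeeping rows
#'   (matrix input); at least one required.
#' @return Normalized counts, same shape as the input; scale factors
#'   in attribute `"scale_factors"`.
#' @export
normalize_counts <- function(counts, housekeeping = NULL) {
  dm <- de_matrix(counts)
  hk <- housekeeping %||% dm$hk
  if (is.null(hk) || !any(hk)) {
    stop("need at least one housekeeping gene", call. = FALSE)
  }
  h <- dm$m[hk, , drop = FALSE]
  if (any(h == 0)) {
    message("zero housekeeping count(s): using +0.5 pseudocount for ",
      "scale factors"
    )
    h <- h + 0.5
  }
  sample_gm <- apply(h, 2, geometric_mean)
  factors <- geometric_mean(as.vector(h)) / sample_gm
  norm <- sweep(dm$m, 2, factors, `*`)
  out <- if (is.matrix(counts)) {
    norm
  } else {
    res <- counts
    res[, colnames(norm)] <- tibble::as_tibble(norm)
    res
  }
  attr(out, "scale_factors") <- factors
  out
}

#' Two-group differential expression on log2 counts
#'
#' For each gene: `log2fc = mean(log2(A + 1)) - mean(log2(B + 1))`
#' (group A is the treatment, B the control) with a two-sided Welch
#' (unequal-variance) t-test on the same log2 scale. The linear-scale
#' `fold_change` uses the signed-reciprocal convention: ratios below 1
#' are reported as the negative reciprocal (a halving is -2, not 0.5).
#' Genes constant and equal across both groups get `p = 1`.
#'
#' @param norm Normalized counts (tibble or matrix, as in
#'   [normalize_counts()]).
#' @param groups Named (or positionally aligned) group label per
#'   sample column.
#' @param group_a,group_b Labels of the treatment and control groups;
#'   each needs >= 2 samples.
#' @return A tibble: `gene`, `log2fc`, `fold_change`, `p`.
#' @export
de_test <- function(norm, groups, group_a, group_b) {
  dm <- de_matrix(norm)
  m <- dm$m
  if (!is.null(names(groups))) {
    groups <- groups[colnames(m)]
  }
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  y <- log2(m + 1)
  purrr::map_dfr(seq_len(nrow(y)), function(i) {
    a <- y[i, ia]
    b <- y[i, ib]
    l2fc <- mean(a) - mean(b)
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (abs(l2fc) < 1e-12) 1 else 0
    } else {
      tryCatch(
        stats::t.test(a, b, var.equal = FALSE)$p.value,
        error = function(e) 1
      )
    }
    tibble::tibble(
      gene = rownames(y)[i],
      log2fc = l2fc,
      fold_change = if (l2fc >= 0) 2^l2fc else -2^(-l2fc),
      p = p
    )
  })
}

#' Benjamini–Hochberg adjusted p-values
#'
#' The step-up FDR adjustment
#' `q(i) = min_{j >= i} (m / j) p(j)` (capped at 1, order-preserving),
#' delegated to [stats::p.adjust()].
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Apply the significance cut-offs to a DE table
#'
#' Adds BH-adjusted p-values (if `p_adj` is absent) and the
#' `significant` flag — `|fold_change| >= fc_cut` AND `p_adj <= alpha`,
#' with the alpha comparison inclusive — then returns the significant
#' genes.
#'
#' @param results DE tibble from [de_test()] (columns `fold_change`,
#'   `p`).
#' @param fc_cut Linear fold-change cut-off, default 1.5.
#' @param alpha Adjusted-p cut-off, default 0.05 (inclusive).
#' @return The significant subset of `results`, with `p_adj` and
#'   `significant` columns.
#' @export
threshold_de <- function(results, fc_cut = 1.5, alpha = 0.05) {
  stopifnot(all(c("fold_change", "p") %in% names(results)))
  if (nrow(results) == 0) {
    return(dplyr::mutate(results,
      p_adj = numeric(0), significant = logical(0)
    ))
  }
  out <- results
  if (!"p_adj" %in% names(out)) out$p_adj <- bh_adjust(out$p)
  out$significant <- abs(out$fold_change) >= fc_cut & out$p_adj <= alpha
  dplyr::filter(out, .data$significant)
}

#' One-call differential expression screen
#'
#' Normalize ([normalize_counts()]), test every gene
#' ([de_test()]), adjust ([bh_adjust()]) and flag significance at the
#' fold-change / adjusted-p cut-offs. Returns the full gene table (use
#' [threshold_de()] for the significant subset).
#'
#' @inheritParams normalize_counts
#' @inheritParams de_test
#' @inheritParams threshold_de
#' @return A tibble: `gene`, `log2fc`, `fold_change`, `p`, `p_adj`,
#'   `significant`.
#' @export
de_screen <- function(counts, groups, group_a, group_b,
                      housekeeping = NULL, fc_cut = 1.5, alpha = 0.05) {
  norm <- normalize_counts(counts, housekeeping)
  res <- de_test(norm, groups, group_a, group_b)
  res$p_adj <- bh_adjust(res$p)
  res$significant <- abs(res$fold_change) >= fc_cut & res$p_adj <= alpha
  res
}

#' Hierarchical leaf ordering for heatmap export
#'
#' Average-linkage agglomerative clustering of the matrix columns under
#' the correlation distance `1 - Pearson`; a constant column has an
#' undefined correlation and gets distance 1 to everything. The
#' ordering is deterministic.
#'
#' @param m Numeric matrix with at least 2 columns.
#' @param linkage Agglomeration method, default `"average"`.
#' @return Character vector of column names in dendrogram leaf order
#'   (column indices if unnamed).
#' @export
hcluster_order <- function(m, linkage = "average") {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns", call. = FALSE)
  cors <- suppressWarnings(stats::cor(m))
  cors[!is.finite(cors)] <- 0 # constant column: distance 1 by convention
  hc <- stats::hclust(stats::as.dist(1 - cors), method = linkage)
  labs <- colnames(m) %||% as.character(seq_len(ncol(m)))
  labs[hc$order]
}
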