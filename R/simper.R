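simper_contrib <- function(x, ia, ib) {
  m <- ncol(x)
  acc <- numeric(m)
  for (a in ia) {
    xa <- x[a, ]
    for (b in ib) {
      xb <- x[b, ]
      acc <- acc + abs(xa - xb) / sum(xa + xb)
    }
  }
  acc / (length(ia) * length(ib))
}

#' SIMPER: decompose between-group dissimilarity by cell type
#'
#' Similarity-percentages analysis: the mean Bray–Curtis dissimilarity
#' between two groups decomposes exactly into per-category
#' contributions — category i contributes the mean over all cross-group
#' sample pairs (a, b) of `|x_ai - x_bi| / sum_k(x_ak + x_bk)` — so the
#' contributions sum to the mean between-group dissimilarity. Each
#' category also gets a permutation p-value: the proportion of group
#' label permutations whose contribution is at least the observed one
#' (add-one corrected), measuring whether the samples contribute
#' consistently.
#'
#' @param comp A long composition tibble (see [composition()]) with the
#'   grouping column `group_col`, or a samples-by-categories matrix
#'   (then supply `groups`).
#' @param group_a,group_b The two group labels to contrast; both need
#'   at least 2 samples.
#' @param groups Group labels per sample, required when `comp` is a
#'   matrix.
#' @param n_perm Number of label permutations, default 999.
#' @param seed Integer seed.
#' @param group_col Grouping column in a tibble `comp`.
#' @return A tibble of class `plex_simper` with one row per category:
#'   `cell_type`, `contribution` (to mean dissimilarity), `percent`
#'   (share of the total), `p_value`; attributes `mean_dissimilarity`,
#'   `n_perm`, `seed`.
#' @export
simper <- function(comp, group_a, group_b, groups = NULL, n_perm = 999,
                   seed = 1, group_col = "subtype") {
  if (is.matrix(comp)) {
    x <- comp
    if (is.null(groups)) {
      stop("supply `groups` when `comp` is a matrix", call. = FALSE)
    }
  } else {
    stopifnot(group_col %in% names(comp), "sample_id" %in% names(comp))
    x <- composition_matrix(comp)
    meta <- unique(comp[, c("sample_id", group_col)])
    groups <- stats::setNames(
      as.character(meta[[group_col]]), meta$sample_id
    )[rownames(x)]
  }
  groups <- as.character(groups)
  keep <- groups %in% c(group_a, group_b)
  x <- x[keep, , drop = FALSE]
  groups <- groups[keep]
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  obs <- simper_contrib(x, ia, ib)
  total <- sum(obs)
  exceed <- integer(length(obs))
  with_seed(seed, {
    n <- length(groups)
    for (p in seq_len(n_perm)) {
      idx <- sample(n)
      pa <- idx[seq_along(ia)]
      pb <- idx[-seq_along(ia)]
      exceed <- exceed + (simper_contrib(x, pa, pb) >= obs)
    }
  })
  out <- tibble::tibble(
    cell_type = colnames(x),
    contribution = unname(obs),
    percent = 100 * unname(obs) / total,
    p_value = (exceed + 1) / (n_perm + 1)
  ) |>
    dplyr::arrange(dplyr::desc(.data$contribution))
  attr(out, "mean_dissimilarity") <- total
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("plex_simper", class(out))
  out
}
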