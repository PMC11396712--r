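permanova_f <- function(d2, groups, levels, n_per) {
  n <- nrow(d2)
  g <- length(levels)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (i in seq_along(levels)) {
    idx <- groups == levels[i]
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * n_per[i])
  }
  ss_among <- ss_total - ss_within
  unname((ss_among / (g - 1)) / (ss_within / (n - g)))
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' One-way PERMANOVA: partitions the total sum of squared
#' dissimilarities (`SS_total = sum(d^2)/n` over unordered pairs) into
#' within- and among-group parts and forms the pseudo-F
#' `(SS_A/(g-1)) / (SS_W/(n-g))`. Significance comes from seeded random
#' permutations of the group labels, with the add-one correction
#' `p = (#(F_perm >= F_obs) + 1) / (n_perm + 1)`, so p is never zero
#' and never smaller than `1/(n_perm + 1)`.
#'
#' @param d A `plex_dist`, `dist` or symmetric distance matrix.
#' @param groups Group labels, one per sample; at least 2 groups with
#'   at least 2 samples each (a singleton group has no within-group
#'   dissimilarities and is an error).
#' @param n_perm Number of permutations, default 9999.
#' @param seed Integer seed.
#' @return An object of class `plex_permtest`: `statistic` (pseudo-F),
#'   `p_value`, `n_perm`, `seed`, `df` (among, within), `ss` (among,
#'   within, total), `method`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  levels <- unique(groups)
  g <- length(levels)
  if (g < 2) stop("need at least two groups", call. = FALSE)
  n_per <- vapply(levels, function(l) sum(groups == l), integer(1))
  if (any(n_per < 2)) {
    stop("every group needs at least 2 samples (no within-group ",
      "distances otherwise)",
      call. = FALSE
    )
  }
  d2 <- dm^2
  f_obs <- permanova_f(d2, groups, levels, n_per)

  # vectorized permutation null: for each level, an n x n_perm
  # indicator matrix Z gives the within-level sums as colSums((d2 Z) * Z)
  perm_labels <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(groups), character(n))
  })
  ss_total <- sum(d2) / (2 * n)
  ss_w_perm <- numeric(n_perm)
  for (i in seq_along(levels)) {
    z <- perm_labels == levels[i]
    storage.mode(z) <- "double"
    ss_w_perm <- ss_w_perm + colSums((d2 %*% z) * z) / (2 * n_per[i])
  }
  f_perm <- ((ss_total - ss_w_perm) / (g - 1)) / (ss_w_perm / (n - g))
  # tie tolerance: permutations equivalent to the observed partition
  # must count as >= despite summation-order rounding
  eps <- if (is.finite(f_obs)) {
    sqrt(.Machine$double.eps) * max(1, abs(f_obs))
  } else {
    0
  }
  p <- (sum(f_perm >= f_obs - eps) + 1) / (n_perm + 1)

  ss_within <- 0
  for (i in seq_along(levels)) {
    idx <- groups == levels[i]
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * unname(n_per[i]))
  }
  structure(
    list(
      statistic = f_obs, p_value = p, n_perm = n_perm, seed = seed,
      df = c(among = g - 1, within = n - g),
      ss = c(
        among = unname(ss_total - ss_within), within = unname(ss_within),
        total = unname(ss_total)
      ),
      method = "permanova"
    ),
    class = "plex_permtest"
  )
}

#' @export
print.plex_permtest <- function(x, ...) {
  cat("<plex_permtest> ", x$method, ": statistic = ",
    signif(x$statistic, 5), ", p = ", signif(x$p_value, 4),
    " (", x$n_perm, " permutations, seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Restricts the distance matrix to each pair of groups and runs
#' [permanova()] on the subset. P-values are reported raw (no
#' multiplicity adjustment).
#'
#' @inheritParams permanova
#' @return A tibble with one row per pair: `group1`, `group2`,
#'   `statistic`, `p_value`, `n_perm`, `seed`.
#' @export
permanova_pairwise <- function(d, groups, n_perm = 9999, seed = 1) {
  dm <- as_dist_matrix(d)
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) < 2) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    idx <- groups %in% pr
    res <- permanova(dm[idx, idx, drop = FALSE], groups[idx],
      n_perm = n_perm, seed = seed
    )
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      statistic = res$statistic, p_value = res$p_value,
      n_perm = n_perm, seed = seed
    )
  })
}
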