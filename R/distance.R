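#' Bray–Curtis dissimilarity between two compositions
#'
#' `sum(|a - b|) / sum(a + b)` over a shared category set: 0 for
#' identical vectors, 1 for disjoint supports, and bounded in `[0, 1]`
#' for any nonnegative input.
#'
#' @param a,b Nonnegative numeric vectors over the same categories (if
#'   named, names must agree; `b` is reordered to match `a`).
#' @return The dissimilarity, a single number in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) {
    stop("compositions must share a category set", call. = FALSE)
  }
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("compositions must share a category set", call. = FALSE)
    }
    b <- b[names(a)]
  }
  if (any(a < 0) || any(b < 0)) {
    stop("compositions must be nonnegative", call. = FALSE)
  }
  if (sum(a) == 0 || sum(b) == 0) {
    stop("Bray–Curtis undefined for an all-zero composition",
      call. = FALSE
    )
  }
  sum(abs(a - b)) / sum(a + b)
}

#' Pairwise Bray–Curtis distance matrix
#'
#' @param comp A long composition tibble (see [composition()]), or a
#'   nonnegative samples-by-categories matrix.
#' @param id Stratum column used for rows when `comp` is a tibble.
#' @return A symmetric matrix of class `plex_dist` with zero diagonal,
#'   labelled by sample, and a `method` attribute.
#' @export
bc_distance_matrix <- function(comp, id = "sample_id") {
  m <- if (is.matrix(comp)) comp else composition_matrix(comp, id = id)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  structure(d, class = c("plex_dist", "matrix"), method = "bray_curtis")
}

#' @export
print.plex_dist <- function(x, ...) {
  cat("<plex_dist> ", attr(x, "method"), ", ", nrow(x), " samples\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  d
}
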