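#' Centred log-ratio transform of a composition
#'
#' `ln(x_i / g(x))` with `g` the geometric mean, mapping a composition
#' to an unconstrained zero-sum vector. Zeros are handled by
#' multiplicative replacement: zero proportions become
#' `zero_replacement` (default: half the smallest nonzero proportion of
#' the input) and the nonzero proportions are shrunk by the common
#' factor that keeps the vector summing to 1.
#'
#' @param x Nonnegative composition (any scale; closed internally).
#' @param zero_replacement Replacement proportion for zeros; `NULL`
#'   picks half the smallest nonzero proportion.
#' @return A numeric vector summing to zero (within 1e-10).
#' @export
clr <- function(x, zero_replacement = NULL) {
  if (any(x < 0)) stop("composition must be nonnegative", call. = FALSE)
  if (sum(x) == 0) stop("all-zero composition", call. = FALSE)
  p <- x / sum(x)
  z <- p == 0
  if (any(z)) {
    delta <- zero_replacement %||% (min(p[!z]) / 2)
    if (delta <= 0 || delta * sum(z) >= 1) {
      stop("invalid zero replacement", call. = FALSE)
    }
    p[z] <- delta
    p[!z] <- p[!z] * (1 - delta * sum(z))
  }
  lp <- log(p)
  out <- lp - mean(lp)
  names(out) <- names(x)
  out
}

#' Per-cell-type ANOVA of CLR-transformed compositions
#'
#' Transforms a samples-by-categories composition matrix row-wise with
#' the centred log-ratio (one shared zero-replacement value: half the
#' smallest nonzero proportion in the whole matrix) and runs a one-way
#' fixed-effects ANOVA of each CLR coordinate on the group labels. A
#' category with zero residual variance but distinct group means is
#' reported with `statistic = Inf`, `p_value = 0` and `flagged = TRUE`.
#'
#' @param comp A long composition tibble with `group_col`, or a
#'   samples-by-categories matrix (then supply `groups`).
#' @param groups Group labels per sample (matrix input).
#' @param group_col Grouping column for tibble input; default
#'   `"subtype"`.
#' @return A tibble: `cell_type`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `flagged`.
#' @export
clr_anova <- function(comp, groups = NULL, group_col = "subtype") {
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
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("need at least 2 groups with at least 2 samples each",
      call. = FALSE
    )
  }
  p <- x / rowSums(x)
  nz <- p[p > 0]
  delta <- min(nz) / 2
  y <- t(apply(p, 1, clr, zero_replacement = delta))
  g <- nlevels(groups)
  n <- nrow(y)
  purrr::map_dfr(colnames(y), function(ct) {
    v <- y[, ct]
    fit <- stats::aov(v ~ groups)
    tab <- summary(fit)[[1]]
    ms_between <- tab[1, "Mean Sq"]
    ms_within <- tab[2, "Mean Sq"]
    if (ms_within < 1e-12 * max(ms_between, 1)) {
      flagged <- TRUE
      f <- if (ms_between < 1e-12) NaN else Inf
      pv <- if (is.nan(f)) 1 else 0
    } else {
      flagged <- FALSE
      f <- tab[1, "F value"]
      pv <- tab[1, "Pr(>F)"]
    }
    tibble::tibble(
      cell_type = ct, statistic = f, df1 = g - 1, df2 = n - g,
      p_value = pv, flagged = flagged
    )
  })
}
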