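#' Fisher's exact test for cell-count contingency tables
#'
#' Two-sided test of independence for an r x c table of nonnegative
#' integer counts with positive margins. A 2 x 2 table is tested
#' exactly: the first cell's conditional distribution given the margins
#' is hypergeometric, and the two-sided p-value is the total
#' probability of all tables whose point probability does not exceed
#' the observed one (the point-probability method). Larger tables are
#' tested by seeded Monte Carlo: `n_mc` tables are drawn uniformly from
#' the fixed-margin conditional distribution and
#' `p = (#(P(T) <= P(obs)) + 1) / (n_mc + 1)`.
#'
#' @param table Matrix of nonnegative integer counts.
#' @param n_mc Monte-Carlo sample size for tables larger than 2 x 2;
#'   default 1e5.
#' @param seed Integer seed (Monte-Carlo branch only).
#' @return An object of class `plex_fisher`: `p_value`, `method`
#'   (`"exact"` or `"monte_carlo"`), `n_mc`, `seed`.
#' @export
fisher_exact <- function(table, n_mc = 1e5, seed = 1) {
  x <- as.matrix(table)
  if (any(x < 0) || any(x != round(x))) {
    stop("table must hold nonnegative integer counts", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  eps <- 1 + 1e-7
  if (all(dim(x) == c(2, 2))) {
    n <- sum(x)
    k <- seq(max(0, rs[1] + cs[1] - n), min(rs[1], cs[1]))
    probs <- stats::dhyper(k, cs[1], n - cs[1], rs[1])
    p_obs <- stats::dhyper(x[1, 1], cs[1], n - cs[1], rs[1])
    p <- sum(probs[probs <= p_obs * eps])
    return(structure(
      list(p_value = min(p, 1), method = "exact", n_mc = NA_integer_,
        seed = NA_integer_
      ),
      class = "plex_fisher"
    ))
  }
  log_p_table <- function(tab) {
    sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
      lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
  }
  lp_obs <- log_p_table(x)
  hits <- with_seed(seed, {
    sims <- stats::r2dtable(n_mc, rs, cs)
    sum(vapply(sims, log_p_table, numeric(1)) <= lp_obs + log(eps))
  })
  structure(
    list(
      p_value = (hits + 1) / (n_mc + 1), method = "monte_carlo",
      n_mc = as.integer(n_mc), seed = as.integer(seed)
    ),
    class = "plex_fisher"
  )
}

#' @export
print.plex_fisher <- function(x, ...) {
  cat("<plex_fisher> p = ", signif(x$p_value, 5), " (", x$method,
    if (x$method == "monte_carlo") paste0(", n_mc = ", x$n_mc), ")\n",
    sep = ""
  )
  invisible(x)
}
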