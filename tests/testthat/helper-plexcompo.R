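# Independent oracles and small fixtures shared across the test files.
# Every oracle here is written directly from the defining formula, with
# plain loops, so it shares no code path with the package functions it
# checks.

# Brute-force Benjamini-Hochberg: for each p_i, the minimum over all
# p_j >= p_i of m * p_j / rank(p_j), capped at 1 (ranks counted with
# ties as the largest rank of the tied block).
bf_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- vapply(p[p >= pi], function(pj) {
      m * pj / sum(p <= pj)
    }, numeric(1))
    min(1, cand)
  }, numeric(1))
}

# PERMANOVA pseudo-F written out with explicit pair loops.
bf_permanova_f <- function(dmat, groups) {
  n <- nrow(dmat)
  lev <- unique(groups)
  ss_total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) ss_total <- ss_total + dmat[i, j]^2
  }
  ss_total <- ss_total / n
  ss_within <- 0
  for (l in lev) {
    idx <- which(groups == l)
    s <- 0
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a < b) s <- s + dmat[idx[a], idx[b]]^2
      }
    }
    ss_within <- ss_within + s / length(idx)
  }
  ((ss_total - ss_within) / (length(lev) - 1)) /
    (ss_within / (n - length(lev)))
}

# Exact PERMANOVA p for two equal groups: full enumeration of every
# assignment of n/2 samples to group A (each equally likely under
# label permutation).
bf_permanova_exact_p <- function(dmat, groups) {
  lev <- unique(groups)
  stopifnot(length(lev) == 2)
  n <- nrow(dmat)
  na <- sum(groups == lev[1])
  f_obs <- bf_permanova_f(dmat, groups)
  combos <- utils::combn(n, na, simplify = FALSE)
  f_all <- vapply(combos, function(ia) {
    g <- rep(lev[2], n)
    g[ia] <- lev[1]
    bf_permanova_f(dmat, g)
  }, numeric(1))
  mean(f_all >= f_obs - 1e-12)
}

# SIMPER contributions written out pair by pair.
bf_simper_contrib <- function(x, ia, ib) {
  m <- ncol(x)
  out <- numeric(m)
  for (k in seq_len(m)) {
    vals <- c()
    for (a in ia) {
      for (b in ib) {
        vals <- c(vals, abs(x[a, k] - x[b, k]) / sum(x[a, ] + x[b, ]))
      }
    }
    out[k] <- mean(vals)
  }
  out
}

# Random composition matrix (rows sum to 100).
rcomp <- function(n, m, seed = NULL) {
  draw <- function() {
    x <- matrix(stats::rgamma(n * m, shape = 2), n, m)
    x <- 100 * x / rowSums(x)
    rownames(x) <- paste0("s", seq_len(n))
    colnames(x) <- paste0("t", seq_len(m))
    x
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Bimodal intensity fixture: two log-normal components given by
# natural-scale moments, with the truth labels.
make_bimodal <- function(n, w_pos, neg = c(1, 0.6), pos = c(15, 4),
                         seed = 1) {
  withr::with_seed(seed, {
    is_pos <- stats::runif(n) < w_pos
    ln <- function(m, s) {
      s2 <- log(1 + (s / m)^2)
      stats::rlnorm(sum_i, log(m) - s2 / 2, sqrt(s2))
    }
    x <- numeric(n)
    sum_i <- sum(!is_pos)
    x[!is_pos] <- ln(neg[1], neg[2])
    sum_i <- sum(is_pos)
    x[is_pos] <- ln(pos[1], pos[2])
    list(values = x, positive = is_pos)
  })
}

# Tiny phenotyped cell table built by hand.
toy_cells <- function(counts, sample_id = "s1", subtype = "A",
                      compartment = "dermis") {
  tibble::tibble(
    sample_id = sample_id,
    subtype = subtype,
    compartment = compartment,
    phenotype = rep(names(counts), counts)
  )
}
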