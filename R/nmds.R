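#' Non-metric multidimensional scaling by Kruskal stress minimization
#'
#' Embeds a dissimilarity matrix in `k` dimensions so that the rank
#' order of configuration distances matches the rank order of the
#' dissimilarities. Each iteration fits a monotone (isotonic,
#' pool-adjacent-violators) regression of configuration distances on
#' the dissimilarity order — ties handled by the primary approach, i.e.
#' tied dissimilarities impose no mutual ordering constraint — and then
#' moves the configuration toward the fitted distances with a Guttman
#' transform, halving the step whenever Kruskal stress-1 would rise, so
#' the reported stress is non-increasing within a run. The first
#' restart starts from classical metric scaling (principal coordinates)
#' of the dissimilarities; later restarts add seeded jitter; the best
#' restart by final stress is returned, rotated to its principal axes.
#'
#' Stress-1 is
#' `sqrt(sum((d - dhat)^2) / sum(d^2))` over all pairs, with `d` the
#' configuration distances and `dhat` the monotone-fitted values.
#'
#' @param d A `plex_dist`, `dist` or symmetric matrix, at least
#'   `k + 2` samples.
#' @param k Embedding dimension, default 2.
#' @param n_restarts Number of starts (default 20).
#' @param max_iter,tol Per-restart iteration cap (default 200) and
#'   stress-change convergence tolerance (default 1e-6).
#' @param seed Integer seed controlling restart jitter.
#' @return An object of class `plex_nmds`: `points` (n x k coordinate
#'   matrix), `stress`, `n_iter`, `converged`, `seed`, `k`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 200, tol = 1e-6,
                 seed = 1) {
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  if (n < k + 2) {
    stop("need at least k + 2 = ", k + 2, " samples", call. = FALSE)
  }
  lower <- which(lower.tri(dm))
  diss <- dm[lower]
  base <- suppressWarnings(stats::cmdscale(dm, k = k))
  if (ncol(base) < k) {
    base <- cbind(base, matrix(0, n, k - ncol(base)))
  }
  scale0 <- max(stats::sd(as.vector(base)), 1e-6)

  run_once <- function(x) {
    stress_old <- Inf
    n_iter <- 0L
    converged <- FALSE
    repeat {
      dv <- as.matrix(stats::dist(x))[lower]
      # primary tie treatment: within tied dissimilarities, order by the
      # current configuration distance so ties are unconstrained
      ord <- order(diss, dv)
      dhat <- numeric(length(dv))
      dhat[ord] <- stats::isoreg(dv[ord])$yf
      denom <- sum(dv^2)
      stress <- if (denom > 0) sqrt(sum((dv - dhat)^2) / denom) else 0
      if (stress_old - stress < tol) {
        converged <- stress_old - stress >= 0 || stress < tol
        stress <- min(stress, stress_old)
        break
      }
      stress_old <- stress
      n_iter <- n_iter + 1L
      if (n_iter >= max_iter) break
      # Guttman transform toward dhat, with step halving as a stress
      # safeguard
      target <- matrix(0, n, n)
      target[lower] <- dhat
      target <- target + t(target)
      dmat <- as.matrix(stats::dist(x))
      ratio <- ifelse(dmat > 0, target / dmat, 0)
      b <- -ratio
      diag(b) <- -rowSums(b)
      x_new <- b %*% x / n
      step <- 1
      repeat {
        x_try <- (1 - step) * x + step * x_new
        dv_try <- as.matrix(stats::dist(x_try))[lower]
        ord_t <- order(diss, dv_try)
        dhat_t <- numeric(length(dv_try))
        dhat_t[ord_t] <- stats::isoreg(dv_try[ord_t])$yf
        den_t <- sum(dv_try^2)
        s_try <- if (den_t > 0) sqrt(sum((dv_try - dhat_t)^2) / den_t) else 0
        if (s_try <= stress_old + 1e-15 || step < 1e-4) break
        step <- step / 2
      }
      x <- x_try
    }
    list(points = x, stress = max(stress_old, 0), n_iter = n_iter,
      converged = converged
    )
  }

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      x0 <- if (r == 1) {
        base
      } else {
        base + matrix(stats::rnorm(n * k, sd = 0.25 * scale0), n, k)
      }
      res <- run_once(x0)
      if (is.null(best) || res$stress < best$stress) best <- res
      if (best$stress < tol) break
    }
  })

  # canonical orientation: centre and rotate to principal axes
  pts <- scale(best$points, scale = FALSE)
  pts <- pts %*% svd(pts)$v
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(
    list(
      points = pts, stress = best$stress, n_iter = best$n_iter,
      converged = best$converged, seed = seed, k = k
    ),
    class = "plex_nmds"
  )
}

#' @export
print.plex_nmds <- function(x, ...) {
  cat("<plex_nmds> k = ", x$k, ", ", nrow(x$points), " samples, stress = ",
    signif(x$stress, 4), if (x$converged) "" else " (not converged)", "\n",
    sep = ""
  )
  invisible(x)
}
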