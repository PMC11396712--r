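#' Hyperbolic arcsine transform of marker intensities
#'
#' `asinh(x / cofactor)`: approximately linear near zero and logarithmic
#' for large intensities, the standard variance-stabilizing transform
#' for fluorescence data. Strictly increasing, so it preserves the order
#' of intensities and never changes which cells are brighter.
#'
#' @param x Numeric intensities (negative values are allowed
#'   mathematically but trigger a warning).
#' @param cofactor Positive scale divisor; default 1.
#' @return `asinh(x / cofactor)`.
#' @export
asinh_transform <- function(x, cofactor = 1) {
  assert_scalar_number(cofactor, "cofactor", positive = TRUE)
  if (any(x < 0, na.rm = TRUE)) {
    warning("negative intensities passed to asinh_transform()", call. = FALSE)
  }
  asinh(x / cofactor)
}

# Per-component log-density on the working scale. For the lognormal
# family EM runs on log(x) with normal machinery; densities here are on
# the original scale so log-likelihoods are comparable across families.
component_logdens <- function(family, x, p1, p2) {
  switch(family,
    normal = stats::dnorm(x, p1, p2, log = TRUE),
    lognormal = stats::dlnorm(x, p1, p2, log = TRUE),
    weibull = stats::dweibull(x, shape = p1, scale = p2, log = TRUE),
    stop("unknown family: ", family, call. = FALSE)
  )
}

# Weighted Weibull maximum-likelihood M-step: profile the shape with
# uniroot, then the scale in closed form. Values are rescaled by their
# maximum before exponentiation to avoid overflow at large shapes; the
# previous iteration's shape warm-starts the root bracket.
weibull_mstep <- function(x, w, k_prev = NULL) {
  sw <- sum(w)
  mlog <- sum(w * log(x)) / sw
  z <- x / max(x)
  h <- function(k) {
    zk <- w * z^k
    sum(zk * log(x)) / sum(zk) - 1 / k - mlog
  }
  lo <- 0.05
  hi <- 50
  if (!is.null(k_prev) && is.finite(k_prev)) {
    blo <- max(lo, k_prev / 1.5)
    bhi <- min(hi, k_prev * 1.5)
    if (blo < bhi && h(blo) < 0 && h(bhi) > 0) {
      lo <- blo
      hi <- bhi
    }
  }
  if (h(lo) > 0 || h(hi) < 0) stop("weibull shape out of range", call. = FALSE)
  k <- stats::uniroot(h, c(lo, hi), tol = 1e-8)$root
  scale <- (sum(w * x^k) / sw)^(1 / k)
  c(k, scale)
}

# One EM run from given initial responsibilities. Returns params (2x2),
# weights, loglik trace, convergence flag; stops on degenerate
# components (vanishing scale or weight).
em_run <- function(x, family, resp, max_iter, tol) {
  n <- length(x)
  work <- if (family == "lognormal") log(x) else x
  jac <- if (family == "lognormal") sum(log(x)) else 0
  scale_floor <- 1e-8 * max(stats::sd(work), .Machine$double.eps)
  params <- matrix(NA_real_, 2, 2)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- colMeans(resp)
    if (any(w < 1e-6) || any(w > 1 - 1e-6)) {
      stop("degenerate component weight", call. = FALSE)
    }
    for (j in 1:2) {
      rj <- resp[, j]
      if (family == "weibull") {
        params[j, ] <- weibull_mstep(x, rj, k_prev = params[j, 1])
      } else {
        mu <- sum(rj * work) / sum(rj)
        s2 <- sum(rj * (work - mu)^2) / sum(rj)
        params[j, ] <- c(mu, sqrt(s2))
      }
      if (!is.finite(params[j, 2]) || params[j, 2] < scale_floor) {
        stop("degenerate component scale", call. = FALSE)
      }
    }
    # E-step on the working scale (normal for the lognormal family)
    fam_work <- if (family == "lognormal") "normal" else family
    l1 <- log(w[1]) + component_logdens(fam_work, work, params[1, 1], params[1, 2])
    l2 <- log(w[2]) + component_logdens(fam_work, work, params[2, 1], params[2, 2])
    norm <- log_sum_exp2(l1, l2)
    ll <- sum(norm) - jac
    resp <- cbind(exp(l1 - norm), exp(l2 - norm))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(
    params = params, weights = w, loglik = trace[length(trace)],
    trace = trace, converged = converged, n_iter = length(trace)
  )
}

# Initial responsibilities for restart r: a k-means split first, then a
# high-quantile cut (so a rare positive population is found even when
# k-means splits the background bulk), then random quantile cuts. Hard
# assignments are softened slightly so no component starts empty.
init_resp <- function(work, restart) {
  n <- length(work)
  if (restart == 1L) {
    km <- tryCatch(
      stats::kmeans(work, centers = 2, nstart = 1),
      error = function(e) NULL
    )
    lab <- if (is.null(km)) {
      as.integer(work > stats::median(work)) + 1L
    } else {
      # component 1 = lower-mean cluster
      lo <- which.min(km$centers)
      ifelse(km$cluster == lo, 1L, 2L)
    }
  } else {
    q <- if (restart == 2L) 0.95 else stats::runif(1, 0.2, 0.98)
    cut <- stats::quantile(work, q)
    lab <- as.integer(work > cut) + 1L
  }
  if (length(unique(lab)) < 2) lab[which.max(work)] <- 2L
  resp <- cbind(0.9 * (lab == 1L) + 0.05, 0.9 * (lab == 2L) + 0.05)
  resp / rowSums(resp)
}

#' Fit a two-component finite mixture to marker intensities
#'
#' EM estimation of a two-component normal, log-normal or Weibull
#' mixture — the model behind marker gating: the lower-mean component is
#' the negative (background) population, the higher-mean component the
#' positive (stained) population. The log-normal fit runs EM on
#' log-intensities (its log-likelihood and BIC are reported on the
#' original scale, so families are comparable); the Weibull M-step
#' solves the weighted profile likelihood for the shape numerically.
#' The best of `n_restarts` seeded initializations by log-likelihood is
#' returned.
#'
#' Restarts that collapse (a component scale or weight tending to zero)
#' are discarded; if every restart collapses the fit is returned with
#' `status = "failed"`. Components separated by fewer than
#' `min_separation` pooled standard deviations are flagged
#' `low_separation` (typical of a marker absent from the tissue, where
#' both components model one population).
#'
#' @param values Numeric vector, length >= 50; strictly positive for the
#'   log-normal and Weibull families.
#' @param family `"normal"`, `"lognormal"` or `"weibull"`.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` (default 1e-8) or after `max_iter`
#'   (default 500) iterations.
#' @param n_restarts Number of initializations (default 3; the first is
#'   a k-means split, the rest random cuts).
#' @param seed Integer seed for the restarts (global RNG untouched).
#' @param min_separation Pooled-SD separation below which the fit is
#'   flagged `low_separation`; default 2.
#' @param transformed,cofactor Metadata recorded when the values passed
#'   in were asinh-transformed upstream; [posterior_positive()] then
#'   applies the same transform to new intensities.
#' @return An object of class `plex_mixfit`: family, `weights` (negative
#'   then positive component), `params` (2 x 2; `mean`/`sd`,
#'   `meanlog`/`sdlog`, or `shape`/`scale` by family), component `means`
#'   and `vars` on the data scale, `loglik`, `bic`, `n`, `converged`,
#'   `status`, `low_separation`, `separation`, `n_iter`, `loglik_trace`,
#'   `transform`.
#' @seealso [select_model()], [posterior_positive()], [call_positive()]
#' @export
fit_mixture <- function(values, family = c("normal", "lognormal", "weibull"),
                        max_iter = 500, tol = 1e-8, n_restarts = 3,
                        seed = 1, min_separation = 2,
                        transformed = FALSE, cofactor = 1) {
  family <- match.arg(family)
  values <- values[is.finite(values)]
  if (length(values) < 50) {
    stop("need at least 50 finite values to fit a mixture", call. = FALSE)
  }
  if (family %in% c("lognormal", "weibull") && any(values <= 0)) {
    stop("family '", family, "' requires strictly positive values",
      call. = FALSE
    )
  }
  work <- if (family == "lognormal") log(values) else values

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      run <- tryCatch(
        em_run(values, family, init_resp(work, r), max_iter, tol),
        error = function(e) NULL
      )
      if (!is.null(run) &&
        (is.null(best) || run$loglik > best$loglik)) {
        best <- run
      }
    }
  })

  if (is.null(best)) {
    return(structure(
      list(
        family = family, weights = c(NA_real_, NA_real_), params = NULL,
        means = c(NA_real_, NA_real_), vars = c(NA_real_, NA_real_),
        loglik = NA_real_, bic = NA_real_, n = length(values),
        converged = FALSE, status = "failed", low_separation = NA,
        separation = NA_real_, n_iter = 0L, loglik_trace = numeric(0),
        transform = list(applied = transformed, cofactor = cofactor),
        seed = seed
      ),
      class = "plex_mixfit"
    ))
  }

  mom <- t(vapply(
    1:2,
    function(j) family_moments(family, best$params[j, 1], best$params[j, 2]),
    numeric(2)
  ))
  # positive component = larger distribution mean (original scale)
  ord <- order(mom[, "mean"])
  params <- best$params[ord, , drop = FALSE]
  weights <- best$weights[ord]
  means <- mom[ord, "mean"]
  vars <- mom[ord, "var"]
  dimnames(params) <- list(
    c("negative", "positive"),
    switch(family,
      normal = c("mean", "sd"),
      lognormal = c("meanlog", "sdlog"),
      weibull = c("shape", "scale")
    )
  )
  separation <- (means[2] - means[1]) / sqrt(mean(vars))
  structure(
    list(
      family = family,
      weights = stats::setNames(weights, c("negative", "positive")),
      params = params,
      means = stats::setNames(means, c("negative", "positive")),
      vars = stats::setNames(vars, c("negative", "positive")),
      loglik = best$loglik,
      bic = -2 * best$loglik + 5 * log(length(values)),
      n = length(values),
      converged = best$converged,
      status = "ok",
      low_separation = separation < min_separation,
      separation = separation,
      n_iter = best$n_iter,
      loglik_trace = best$trace,
      transform = list(applied = transformed, cofactor = cofactor),
      seed = seed
    ),
    class = "plex_mixfit"
  )
}

#' @export
print.plex_mixfit <- function(x, ...) {
  cat("<plex_mixfit> family = ", x$family,
    ", n = ", x$n, ", status = ", x$status, "\n",
    sep = ""
  )
  if (x$status == "ok") {
    cat(sprintf(
      "  weights  neg %.3f / pos %.3f\n", x$weights[1], x$weights[2]
    ))
    cat(sprintf(
      "  means    neg %.3f / pos %.3f  (separation %.2f pooled SD%s)\n",
      x$means[1], x$means[2], x$separation,
      if (isTRUE(x$low_separation)) ", LOW" else ""
    ))
    cat(sprintf(
      "  loglik %.2f  BIC %.2f  iter %d  converged %s\n",
      x$loglik, x$bic, x$n_iter, x$converged
    ))
  }
  invisible(x)
}

#' Select the best-fitting mixture family by BIC
#'
#' Fits each candidate family with [fit_mixture()] and returns the fit
#' with the smallest BIC — the model-selection stand-in for choosing a
#' distribution "by the shape of the histogram". Ties (within 1e-9)
#' break in the fixed order normal < lognormal < weibull. Families whose
#' fit collapses are skipped; if every family fails an error is raised.
#'
#' @param values Numeric intensities.
#' @param families Character subset of
#'   `c("normal", "lognormal", "weibull")`, in any order.
#' @param seed Integer seed passed to each fit.
#' @param ... Further arguments to [fit_mixture()].
#' @return The winning `plex_mixfit`.
#' @export
select_model <- function(values, families = c("normal", "lognormal", "weibull"),
                         seed = 1, ...) {
  canonical <- c("normal", "lognormal", "weibull")
  families <- canonical[canonical %in% families]
  if (!length(families)) stop("no valid families supplied", call. = FALSE)
  fits <- list()
  for (fam in families) {
    f <- tryCatch(
      fit_mixture(values, family = fam, seed = seed, ...),
      error = function(e) NULL
    )
    if (!is.null(f) && f$status == "ok") fits[[fam]] <- f
  }
  if (!length(fits)) {
    stop("all mixture families failed to fit", call. = FALSE)
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  fits[[which(bics <= min(bics) + 1e-9)[1]]]
}

#' Posterior probability that an intensity is from the positive component
#'
#' The Bayes posterior `w+ f+(x) / (w+ f+(x) + w- f-(x))`, computed with
#' log-densities for numerical stability; the positive component is the
#' one with the larger distribution mean. Intensities below the support
#' of the fitted family (e.g. `x <= 0` for a log-normal) have both
#' densities zero and are assigned posterior 0: an intensity below the
#' support floor cannot be stained signal. If the fit was made on
#' asinh-transformed values the same transform is applied to `x` first.
#'
#' @param fit A converged `plex_mixfit`.
#' @param x Numeric intensities (vectorized).
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_positive <- function(fit, x) {
  stopifnot(inherits(fit, "plex_mixfit"))
  if (fit$status != "ok") {
    stop("cannot compute posteriors from a failed fit", call. = FALSE)
  }
  if (isTRUE(fit$transform$applied)) {
    x <- asinh_transform(x, fit$transform$cofactor)
  }
  l_neg <- log(fit$weights[1]) +
    component_logdens(fit$family, x, fit$params[1, 1], fit$params[1, 2])
  l_pos <- log(fit$weights[2]) +
    component_logdens(fit$family, x, fit$params[2, 1], fit$params[2, 2])
  norm <- log_sum_exp2(l_neg, l_pos)
  post <- exp(l_pos - norm)
  post[is.infinite(norm) & norm < 0] <- 0 # below support of both components
  unname(post)
}

#' Call a cell positive for a marker
#'
#' Positive when the posterior probability of the positive component
#' strictly exceeds `threshold`; a posterior of exactly the threshold is
#' negative.
#'
#' @param fit A converged `plex_mixfit`.
#' @param x Numeric intensities.
#' @param threshold Posterior cut-off in (0, 1); default 0.95.
#' @return Logical vector.
#' @export
call_positive <- function(fit, x, threshold = 0.95) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  posterior_positive(fit, x) > threshold
}
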