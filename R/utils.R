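#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded functions never perturb global random state.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG alone.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Geometric mean of positive values
#' @keywords internal
#' @noRd
geometric_mean <- function(x) exp(mean(log(x)))

#' Moment (Fisher) skewness
#' @keywords internal
#' @noRd
moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(0)
  }
  mean((x - mean(x))^3) / s^3
}

# Convert a (mean, sd) pair on the natural scale into log-normal
# (meanlog, sdlog) parameters.
lnorm_from_moments <- function(m, s) {
  stopifnot(m > 0, s > 0)
  sdlog2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Convert a (mean, sd) pair into Weibull (shape, scale) by solving the
# coefficient-of-variation equation for the shape.
weibull_from_moments <- function(m, s) {
  stopifnot(m > 0, s > 0)
  cv2 <- (s / m)^2
  f <- function(k) gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv2
  k <- stats::uniroot(f, c(0.05, 100), tol = 1e-10)$root
  c(shape = k, scale = m / gamma(1 + 1 / k))
}

# Mean and variance of the named two-parameter family.
family_moments <- function(family, p1, p2) {
  switch(family,
    normal = c(mean = p1, var = p2^2),
    lognormal = {
      m <- exp(p1 + p2^2 / 2)
      c(mean = m, var = (exp(p2^2) - 1) * m^2)
    },
    weibull = {
      m <- p2 * gamma(1 + 1 / p1)
      c(mean = m, var = p2^2 * (gamma(1 + 2 / p1) - gamma(1 + 1 / p1)^2))
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

# log(exp(a) + exp(b)) done stably, elementwise.
log_sum_exp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("`", name, "` must be positive", call. = FALSE)
  }
  invisible(x)
}
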