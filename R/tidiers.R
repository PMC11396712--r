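#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mixture
#'
#' One row per component with the family parameters, data-scale moments
#' and mixing weight.
#'
#' @param x A `plex_mixfit`.
#' @param ... Unused.
#' @return A tibble: `component`, `weight`, the two family parameters,
#'   `dist_mean`, `dist_sd` (data-scale moments).
#' @method tidy plex_mixfit
#' @export
tidy.plex_mixfit <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(
      component = c("negative", "positive"), weight = NA_real_
    ))
  }
  p <- tibble::as_tibble(x$params)
  dplyr::bind_cols(
    tibble::tibble(component = rownames(x$params), weight = unname(x$weights)),
    p,
    tibble::tibble(
      dist_mean = unname(x$means), dist_sd = sqrt(unname(x$vars))
    )
  )
}

#' @rdname tidy.plex_mixfit
#' @return For `glance()`, a one-row tibble: `family`, `loglik`, `bic`,
#'   `n`, `n_iter`, `converged`, `status`, `separation`,
#'   `low_separation`, `transformed`.
#' @method glance plex_mixfit
#' @export
glance.plex_mixfit <- function(x, ...) {
  tibble::tibble(
    family = x$family, loglik = x$loglik, bic = x$bic, n = x$n,
    n_iter = x$n_iter, converged = x$converged, status = x$status,
    separation = x$separation, low_separation = x$low_separation,
    transformed = x$transform$applied
  )
}

#' Tidy a permutation test
#'
#' @param x A `plex_permtest`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `statistic`, `p_value`,
#'   `n_perm`, `seed`.
#' @method tidy plex_permtest
#' @export
tidy.plex_permtest <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    n_perm = x$n_perm, seed = x$seed
  )
}

#' @rdname tidy.plex_permtest
#' @method glance plex_permtest
#' @export
glance.plex_permtest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    df_among = x$df[["among"]], df_within = x$df[["within"]],
    ss_among = x$ss[["among"]], ss_within = x$ss[["within"]],
    ss_total = x$ss[["total"]], n_perm = x$n_perm, seed = x$seed
  )
}

#' Tidy an NMDS ordination
#'
#' @param x A `plex_nmds`.
#' @param ... Unused.
#' @return One row per sample with its coordinates.
#' @method tidy plex_nmds
#' @export
tidy.plex_nmds <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = rownames(x$points) %||%
        as.character(seq_len(nrow(x$points)))
    ),
    tibble::as_tibble(x$points)
  )
}

#' @rdname tidy.plex_nmds
#' @method glance plex_nmds
#' @export
glance.plex_nmds <- function(x, ...) {
  tibble::tibble(
    stress = x$stress, k = x$k, n = nrow(x$points),
    n_iter = x$n_iter, converged = x$converged, seed = x$seed
  )
}

#' Tidy a distance matrix into sample pairs
#'
#' @param x A `plex_dist`.
#' @param ... Unused.
#' @return A tibble of unordered pairs: `sample1`, `sample2`,
#'   `distance`.
#' @method tidy plex_dist
#' @export
tidy.plex_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(
    sample1 = rownames(m)[idx[, "col"]],
    sample2 = rownames(m)[idx[, "row"]],
    distance = m[idx]
  )
}
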