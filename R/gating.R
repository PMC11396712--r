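#' Assign composite phenotypes from per-marker positivity calls
#'
#' Applies a panel's phenotype rules in priority order: the first tier
#' containing a rule whose required markers are all positive decides the
#' phenotype, and cells negative for every marker are `"other"`. When
#' several rules in the same tier match (e.g. a CD68+ pSTAT1+ cMaf+
#' cell matching both M1 and M2), the rule whose distinguishing markers
#' (those not shared by all competing rules) have the higher mean
#' posterior wins; without posteriors the earlier rule wins with a
#' warning.
#'
#' `assign_phenotype()` handles one cell (a named logical vector);
#' `assign_phenotypes()` is the vectorized form used by [gate_cells()].
#'
#' @param calls Named logical vector of marker calls covering exactly
#'   the panel's markers.
#' @param panel A [plex_panel()].
#' @param posteriors Optional named numeric vector of posterior
#'   probabilities (same names as `calls`), used only for within-tier
#'   tie-breaks.
#' @return A phenotype label.
#' @export
assign_phenotype <- function(calls, panel, posteriors = NULL) {
  stopifnot(inherits(panel, "plex_panel"))
  extra <- setdiff(names(calls), panel$markers)
  if (length(extra)) {
    stop("marker(s) absent from the panel definition: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(panel$markers, names(calls))
  if (length(missing)) {
    stop("calls missing panel marker(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  cm <- matrix(calls[panel$markers],
    nrow = 1,
    dimnames = list(NULL, panel$markers)
  )
  pm <- if (!is.null(posteriors)) {
    matrix(posteriors[panel$markers],
      nrow = 1,
      dimnames = list(NULL, panel$markers)
    )
  }
  assign_phenotypes(cm, panel, pm)[1]
}

#' @rdname assign_phenotype
#' @param calls_matrix Logical matrix, cells x markers (columns named
#'   for the panel's markers).
#' @param posterior_matrix Optional numeric matrix of posteriors with
#'   the same shape.
#' @return For `assign_phenotypes()`, a character vector of phenotype
#'   labels, one per row.
#' @export
assign_phenotypes <- function(calls_matrix, panel, posterior_matrix = NULL) {
  stopifnot(inherits(panel, "plex_panel"), is.matrix(calls_matrix))
  extra <- setdiff(colnames(calls_matrix), panel$markers)
  if (length(extra)) {
    stop("marker(s) absent from the panel definition: ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  missing <- setdiff(panel$markers, colnames(calls_matrix))
  if (length(missing)) {
    stop("calls missing panel marker(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(calls_matrix)
  out <- rep("other", n)
  assigned <- rep(FALSE, n)
  tiers <- vapply(panel$rules, `[[`, numeric(1), "tier")
  for (tier in sort(unique(tiers))) {
    rules <- panel$rules[tiers == tier]
    match_mat <- vapply(
      rules,
      function(r) {
        rowSums(!calls_matrix[, r$requires, drop = FALSE]) == 0
      },
      logical(n)
    )
    if (n == 1) match_mat <- matrix(match_mat, nrow = 1)
    match_mat[assigned, ] <- FALSE
    n_match <- rowSums(match_mat)
    if (length(rules) > 1 && any(n_match > 1)) {
      shared <- Reduce(intersect, lapply(rules, `[[`, "requires"))
      scores <- vapply(
        rules,
        function(r) {
          dm <- setdiff(r$requires, shared)
          if (!length(dm) || is.null(posterior_matrix)) {
            return(rep(NA_real_, n))
          }
          rowMeans(posterior_matrix[, dm, drop = FALSE])
        },
        numeric(n)
      )
      if (n == 1) scores <- matrix(scores, nrow = 1)
      tied <- which(n_match > 1)
      if (is.null(posterior_matrix)) {
        warning(
          "within-tier phenotype tie broken by rule order ",
          "(no posteriors supplied)",
          call. = FALSE
        )
        for (i in tied) {
          out[i] <- rules[[which(match_mat[i, ])[1]]]$phenotype
        }
      } else {
        for (i in tied) {
          cand <- which(match_mat[i, ])
          best <- cand[which.max(scores[i, cand])]
          out[i] <- rules[[best]]$phenotype
        }
      }
      assigned[tied] <- TRUE
      match_mat[tied, ] <- FALSE
      n_match <- rowSums(match_mat)
    }
    for (j in seq_along(rules)) {
      hit <- match_mat[, j] & n_match >= 1 & !assigned
      out[hit] <- rules[[j]]$phenotype
      assigned[hit] <- TRUE
    }
  }
  out
}

#' Gate a cell table: mixture fits, posterior calls, phenotypes
#'
#' The per-marker gating pipeline over a whole cell table: for each
#' marker (within each sample by default, or pooled across the cohort),
#' choose and fit a two-component mixture ([select_model()]), compute
#' each cell's posterior probability of being in the positive
#' component, call positivity at `threshold`, and assign composite
#' phenotypes from the panel rules.
#'
#' Intensities are asinh-transformed before fitting only "when
#' required": when the raw histogram's absolute skewness exceeds
#' `asinh_skew` (default 2) but no right-skew-capable family
#' (log-normal or Weibull) is available for the raw values, or as a
#' fallback when every family fails on the raw values. When a
#' log-normal or Weibull candidate can be fitted directly, the raw
#' scale is preferred: transforming and then fitting a generic family
#' is a misspecification that audibly degrades posterior calibration
#' near the gating threshold. Fits flagged low-separation are treated
#' as a marker with no positive population in that unit: all its cells
#' are called negative. This prevents a unimodal background histogram
#' from being split in two and half the tissue called positive.
#'
#' @param cells Cell table (tibble) with a `sample_id` column and one
#'   intensity column per panel marker.
#' @param panel A [plex_panel()].
#' @param mode `"per_sample"` (one fit per marker per sample, robust to
#'   slide-to-slide staining variation) or `"pooled"` (one fit per
#'   marker across all cells).
#' @param families Candidate mixture families for [select_model()].
#' @param threshold Posterior cut-off; calls are strict (`> threshold`).
#' @param asinh_skew Absolute skewness above which intensities are
#'   asinh-transformed before fitting.
#' @param cofactor asinh cofactor.
#' @param seed Integer seed for the EM restarts.
#' @param max_fit_cells Mixtures are fitted on at most this many cells
#'   per unit (a seeded subsample; default 25000 — far beyond the
#'   sample size needed for stable component estimates); posteriors
#'   are then computed for every cell.
#' @param ... Passed on to [fit_mixture()].
#' @return The input tibble with, per marker `M`, numeric `p_M`
#'   (posterior) and logical `pos_M` (call) columns, plus a `phenotype`
#'   column. Fitted models are attached as attribute `"fits"` (a tibble
#'   of unit, marker and `plex_mixfit`).
#' @export
gate_cells <- function(cells, panel, mode = c("per_sample", "pooled"),
                       families = c("normal", "lognormal", "weibull"),
                       threshold = 0.95, asinh_skew = 2, cofactor = 1,
                       seed = 1, max_fit_cells = 25000, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "plex_panel"), is.data.frame(cells))
  missing <- setdiff(panel$markers, names(cells))
  if (length(missing)) {
    stop("cell table lacks intensity column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (mode == "per_sample" && !"sample_id" %in% names(cells)) {
    stop("per-sample gating needs a `sample_id` column", call. = FALSE)
  }
  units <- if (mode == "pooled") {
    list(all = seq_len(nrow(cells)))
  } else {
    split(seq_len(nrow(cells)), cells$sample_id)
  }
  n <- nrow(cells)
  post <- matrix(NA_real_, n, length(panel$markers),
    dimnames = list(NULL, panel$markers)
  )
  fit_log <- list()
  for (u in names(units)) {
    idx <- units[[u]]
    for (mk in panel$markers) {
      x <- cells[[mk]][idx]
      if (length(x) > max_fit_cells) {
        x <- with_seed(seed, sample(x, max_fit_cells))
      }
      skew_capable <- any(c("lognormal", "weibull") %in% families) &&
        all(x > 0)
      use_asinh <- abs(moment_skewness(x)) > asinh_skew && !skew_capable
      fit <- tryCatch(
        select_model(
          if (use_asinh) asinh_transform(x, cofactor) else x,
          families = families, seed = seed,
          transformed = use_asinh, cofactor = cofactor, ...
        ),
        error = function(e) NULL
      )
      if (is.null(fit) && !use_asinh) {
        use_asinh <- TRUE
        fit <- select_model(asinh_transform(x, cofactor),
          families = families, seed = seed,
          transformed = TRUE, cofactor = cofactor, ...
        )
      }
      if (is.null(fit)) {
        stop("gating failed for marker ", mk, " in unit ", u, call. = FALSE)
      }
      post[idx, mk] <- if (isTRUE(fit$low_separation)) {
        0 # unimodal histogram: no positive population in this unit
      } else {
        posterior_positive(fit, cells[[mk]][idx])
      }
      fit_log[[paste(u, mk, sep = ".")]] <- tibble::tibble(
        unit = u, marker = mk, family = fit$family,
        transformed = fit$transform$applied,
        low_separation = fit$low_separation,
        fit = list(fit)
      )
    }
  }
  calls <- post > threshold
  phen <- assign_phenotypes(calls, panel, post)
  out <- cells
  for (mk in panel$markers) {
    out[[paste0("p_", mk)]] <- post[, mk]
    out[[paste0("pos_", mk)]] <- calls[, mk]
  }
  out$phenotype <- phen
  attr(out, "fits") <- dplyr::bind_rows(fit_log)
  attr(out, "gating") <- list(
    mode = mode, threshold = threshold, families = families,
    asinh_skew = asinh_skew, cofactor = cofactor, seed = seed
  )
  out
}
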