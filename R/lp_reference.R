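#' Published pooled cell-type percentages for lichen planus subtypes
#'
#' The pooled dermal cell-type composition of four lichen planus (LP)
#' subtypes (classical/cutaneous, genital, oral, lichen planopilaris)
#' and non-diseased control skin (NDC), as percentages of all segmented
#' cells, printed to three significant figures. These values ship with
#' the package as its reference parameterization: they seed the
#' synthetic-cohort generator ([lp_composition_targets()]) and provide a
#' closed arithmetic check for [derive_totals()] ("Total T cells" is the
#' sum of the five T-lineage categories; M1/M2 are sub-fractions of
#' "Total macrophages", not extra mass).
#'
#' @param include_totals Keep the derived rows ("Total T cells",
#'   "Total macrophages") alongside the mutually exclusive categories.
#'   With `include_totals = FALSE` only exclusive categories are
#'   returned (macrophages appear as the plain `"macrophage"` category,
#'   i.e. total minus the M1/M2 sub-fractions), so percentages sum to
#'   ~100 per subtype.
#' @return A tibble with columns `subtype`, `cell_type`, `percent`.
#' @export
lp_cell_percentages <- function(include_totals = TRUE) {
  subtypes <- c("classical", "genital", "oral", "planopilaris", "NDC")
  rows <- list(
    `Total T cells` = c(48.8, 24.7, 53.0, 7.04, 3.61),
    `CD4+ T` = c(8.5, 3.14, 0.108, 0.069, 0),
    `CD8+ T` = c(6.44, 4.87, 5.27, 2.17, 0.373),
    Treg = c(30.3, 14.6, 39.2, 3.51, 2.29),
    `GranzymeB+` = c(1.15, 0.619, 0.434, 0.110, 0.117),
    `IL17A+` = c(2.39, 1.54, 8.02, 1.18, 0.831),
    keratinocyte = c(24.9, 25.4, 24.6, 54.0, 62.1),
    `Total macrophages` = c(12.3, 9.26, 11.2, 3.96, 0.193),
    M1 = c(0.0397, 0.243, 0.266, 0.0092, 0),
    M2 = c(0.176, 0.191, 0.124, 0.212, 0.0126),
    neutrophil = c(0.301, 2.51, 0.730, 0.446, 0.0084),
    other = c(13.8, 38.1, 10.5, 34.6, 34.1)
  )
  tab <- tibble::tibble(
    cell_type = rep(names(rows), each = length(subtypes)),
    subtype = rep(subtypes, times = length(rows)),
    percent = unlist(rows, use.names = FALSE)
  )
  if (!include_totals) {
    tab <- tab |>
      tidyr::pivot_wider(names_from = "cell_type", values_from = "percent") |>
      dplyr::mutate(
        macrophage = .data$`Total macrophages` - .data$M1 - .data$M2
      ) |>
      dplyr::select(-"Total T cells", -"Total macrophages") |>
      tidyr::pivot_longer(-"subtype",
        names_to = "cell_type", values_to = "percent"
      )
  }
  dplyr::arrange(
    tab,
    factor(.data$subtype, levels = subtypes), .data$cell_type
  )
}

#' Composition targets for the synthetic lichen planus cohort
#'
#' Converts the published pooled percentages ([lp_cell_percentages()]) into
#' per-subtype cell-type proportions over the mutually exclusive
#' phenotype categories (the five T lineages, keratinocytes, plain
#' CD68+ macrophages, M1, M2, neutrophils, "other"), renormalized to sum
#' to exactly 1. These are the default `composition_targets` of
#' [cohort_config()].
#'
#' @return A named list: one named proportion vector per subtype.
#' @export
lp_composition_targets <- function() {
  tab <- lp_cell_percentages(include_totals = FALSE)
  split(tab, factor(tab$subtype, levels = unique(tab$subtype))) |>
    lapply(function(d) {
      p <- stats::setNames(d$percent, d$cell_type)
      p / sum(p)
    })
}

#' Default per-marker intensity mixture models
#'
#' Each marker gets a two-component intensity model: a negative
#' (background) component and a positive (stained) component, both
#' log-normal by default, parameterized by their natural-scale means and
#' standard deviations. The defaults (background mean 1, sd 0.6; signal
#' mean 15, sd 4, in arbitrary fluorescence units) give a 15-fold
#' signal-to-background ratio with ~27% CV, i.e. roughly a 6.5
#' pooled-SD separation on the log scale — the regime of a bright,
#' well-titrated tyramide-amplified stain, where a strict posterior
#' gate loses almost no true positives.
#'
#' @param markers Character vector of marker names.
#' @param family Component family: `"lognormal"` (default), `"normal"`
#'   or `"weibull"`.
#' @param neg_mean,neg_sd,pos_mean,pos_sd Component moments on the raw
#'   intensity scale; recycled across markers.
#' @return A named list of per-marker models
#'   (`neg_mean`, `neg_sd`, `pos_mean`, `pos_sd`, `family`).
#' @export
default_marker_models <- function(markers, family = "lognormal",
                                  neg_mean = 1, neg_sd = 0.6,
                                  pos_mean = 15, pos_sd = 4) {
  stopifnot(is.character(markers), length(markers) > 0)
  n <- length(markers)
  neg_mean <- rep_len(neg_mean, n)
  neg_sd <- rep_len(neg_sd, n)
  pos_mean <- rep_len(pos_mean, n)
  pos_sd <- rep_len(pos_sd, n)
  family <- rep_len(family, n)
  out <- lapply(seq_len(n), function(i) {
    list(
      neg_mean = neg_mean[i], neg_sd = neg_sd[i],
      pos_mean = pos_mean[i], pos_sd = pos_sd[i],
      family = family[i]
    )
  })
  stats::setNames(out, markers)
}
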