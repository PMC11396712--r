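#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an NMDS ordination
#'
#' @param object A `plex_nmds`.
#' @param groups Optional group label per sample for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plex_nmds
#' @export
autoplot.plex_nmds <- function(object, groups = NULL, ...) {
  d <- tidy(object)
  p <- if (is.null(groups)) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  } else {
    d$group <- as.character(groups)
    ggplot2::ggplot(
      d,
      ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2, colour = .data$group)
    )
  }
  p +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      subtitle = sprintf("stress = %.3f", object$stress),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted intensity mixture over its data
#'
#' Histogram of the intensities with the weighted component densities
#' and the fitted posterior-positivity region boundary.
#'
#' @param object A converged `plex_mixfit`.
#' @param values The intensities the model was fitted to (on the scale
#'   passed to [fit_mixture()]).
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plex_mixfit
#' @export
autoplot.plex_mixfit <- function(object, values, bins = 60, ...) {
  stopifnot(object$status == "ok")
  grid <- seq(min(values), max(values), length.out = 400)
  dens <- function(j) {
    object$weights[j] * exp(
      component_logdens(object$family, grid, object$params[j, 1],
        object$params[j, 2]
      )
    )
  }
  curves <- tibble::tibble(
    x = rep(grid, 2),
    density = c(dens(1), dens(2)),
    component = rep(c("negative", "positive"), each = length(grid))
  )
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = values),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey70"
    ) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$x, y = .data$density, colour = .data$component),
      linewidth = 0.8
    ) +
    ggplot2::labs(x = "intensity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked-bar plot of cell-type compositions
#'
#' @param comp A long composition tibble (see [composition()]).
#' @param id Stratum column on the x axis, default `"sample_id"`.
#' @return A ggplot.
#' @export
plot_composition <- function(comp, id = "sample_id") {
  stopifnot(id %in% names(comp))
  ggplot2::ggplot(
    comp,
    ggplot2::aes(
      x = .data[[id]], y = .data$percent, fill = .data$cell_type
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of cells", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}
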