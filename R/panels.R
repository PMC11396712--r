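#' Build a phenotyping panel specification
#'
#' A panel couples the marker list of one multiplex stain with an ordered
#' set of phenotype rules. Rules are evaluated in priority order (lowest
#' `tier` first); the first tier with a match decides the phenotype, and
#' cells negative for every marker fall through to `"other"`. Rules that
#' share a tier (e.g. M1 vs M2 macrophages, which differ only in their
#' polarization marker) are disambiguated by the higher posterior
#' probability of their distinguishing markers.
#'
#' The same rules define the marker signatures used by
#' [simulate_cell_table()]: a simulated cell of a given phenotype is
#' positive for exactly that rule's markers.
#'
#' @param name Panel name.
#' @param markers Character vector of marker (intensity column) names.
#' @param rules A list of rules, each `list(phenotype =, requires =, tier =)`
#'   where `requires` is the character vector of markers that must be
#'   called positive.
#' @return An object of class `plex_panel`.
#' @seealso [tcell_panel()], [macrophage_panel()]
#' @export
plex_panel <- function(name, markers, rules) {
  stopifnot(is.character(markers), length(markers) > 0)
  for (r in rules) {
    if (!all(c("phenotype", "requires", "tier") %in% names(r))) {
      stop("each rule needs `phenotype`, `requires` and `tier`", call. = FALSE)
    }
    bad <- setdiff(r$requires, markers)
    if (length(bad)) {
      stop("rule '", r$phenotype, "' requires markers not in the panel: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  tiers <- vapply(rules, `[[`, numeric(1), "tier")
  rules <- rules[order(tiers)]
  structure(
    list(name = name, markers = markers, rules = rules),
    class = "plex_panel"
  )
}

#' @export
print.plex_panel <- function(x, ...) {
  cat("<plex_panel> ", x$name, "\n", sep = "")
  cat("  markers: ", paste(x$markers, collapse = ", "), "\n", sep = "")
  for (r in x$rules) {
    cat(sprintf(
      "  [%d] %-14s %s\n", r$tier, r$phenotype,
      paste0(r$requires, "+", collapse = " ")
    ))
  }
  cat("  [-] other          (all markers negative)\n")
  invisible(x)
}

#' Phenotypes a panel can assign
#' @param panel A [plex_panel()].
#' @return Character vector of phenotype labels, `"other"` last.
#' @export
panel_phenotypes <- function(panel) {
  stopifnot(inherits(panel, "plex_panel"))
  c(vapply(panel$rules, `[[`, character(1), "phenotype"), "other")
}

#' T-cell panel (CD8, FoxP3, IL17A, GranzymeB, PanCK, CD4)
#'
#' Phenotype priority: Treg (FoxP3+) outranks the cytokine phenotypes
#' (IL17A+, GranzymeB+), which outrank the lineage T-cell phenotypes
#' (CD8+ then CD4+), then keratinocytes (PanCK+); all-negative cells are
#' `"other"`. Categories are therefore mutually exclusive and sum to the
#' whole cell population.
#'
#' @param treg_requires_cd4 If `TRUE`, the Treg rule demands CD4
#'   co-positivity in addition to FoxP3. Default `FALSE` (FoxP3 alone
#'   defines a Treg).
#' @return A `plex_panel`.
#' @export
tcell_panel <- function(treg_requires_cd4 = FALSE) {
  treg_req <- if (treg_requires_cd4) c("FoxP3", "CD4") else "FoxP3"
  plex_panel(
    name = "tcell",
    markers = c("CD8", "FoxP3", "IL17A", "GranzymeB", "PanCK", "CD4"),
    rules = list(
      list(phenotype = "Treg", requires = treg_req, tier = 1),
      list(phenotype = "IL17A+", requires = "IL17A", tier = 2),
      list(phenotype = "GranzymeB+", requires = "GranzymeB", tier = 3),
      list(phenotype = "CD8+ T", requires = "CD8", tier = 4),
      list(phenotype = "CD4+ T", requires = "CD4", tier = 5),
      list(phenotype = "keratinocyte", requires = "PanCK", tier = 6)
    )
  )
}

#' Macrophage/neutrophil panel (pSTAT1, MPO, cMaf, PanCK, CD68)
#'
#' M1 (CD68+ pSTAT1+) and M2 (CD68+ cMaf+) share a priority tier: a cell
#' positive for CD68, pSTAT1 and cMaf is assigned to the polarization
#' whose defining marker has the higher posterior probability. CD68+
#' cells matching neither polarization are `"macrophage"`, MPO+ cells are
#' `"neutrophil"`, PanCK+ cells `"keratinocyte"`, the rest `"other"`.
#'
#' @return A `plex_panel`.
#' @export
macrophage_panel <- function() {
  plex_panel(
    name = "macrophage",
    markers = c("pSTAT1", "MPO", "cMaf", "PanCK", "CD68"),
    rules = list(
      list(phenotype = "M1", requires = c("CD68", "pSTAT1"), tier = 1),
      list(phenotype = "M2", requires = c("CD68", "cMaf"), tier = 1),
      list(phenotype = "macrophage", requires = "CD68", tier = 2),
      list(phenotype = "neutrophil", requires = "MPO", tier = 3),
      list(phenotype = "keratinocyte", requires = "PanCK", tier = 4)
    )
  )
}
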