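T_LINEAGES <- c("CD4+ T", "CD8+ T", "Treg", "GranzymeB+", "IL17A+")
MAC_CATEGORIES <- c("macrophage", "M1", "M2", "neutrophil")

#' Per-stratum cell-type composition
#'
#' Counts phenotyped cells within each stratum (one value of `by`,
#' optionally restricted to one tissue compartment) and converts counts
#' to percentages of all cells in the stratum; `"other"` is always kept
#' as a category. Strata emptied by the compartment filter are omitted
#' with a warning.
#'
#' @param cells Tibble with `phenotype` and (if filtering) `compartment`
#'   columns; a `subtype` column, when present, is carried along as
#'   metadata.
#' @param by Column defining the strata (default `"sample_id"`; use
#'   `"subtype"` for cell-weighted pooling by group).
#' @param compartment `"all"`, `"dermis"` or `"epidermis"`.
#' @param types Category set to tabulate; defaults to the phenotypes
#'   observed plus `"other"`. Absent categories get percentage 0.
#' @return A long tibble — one row per stratum x cell type — with
#'   columns `by`, (`subtype`), `compartment`, `cell_type`, `n`,
#'   `n_cells` (stratum total) and `percent`. Percentages sum to 100
#'   per stratum.
#' @export
composition <- function(cells, by = "sample_id",
                        compartment = c("all", "dermis", "epidermis"),
                        types = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(is.data.frame(cells), by %in% names(cells))
  if (!"phenotype" %in% names(cells)) {
    stop("cells must carry a `phenotype` column (run gate_cells() first)",
      call. = FALSE
    )
  }
  all_strata <- unique(cells[[by]])
  if (compartment != "all") {
    if (!"compartment" %in% names(cells)) {
      stop("no `compartment` column to filter on", call. = FALSE)
    }
    cells <- cells[cells$compartment == compartment, , drop = FALSE]
  }
  if (is.null(types)) {
    types <- union(sort(unique(cells$phenotype)), "other")
  }
  lost <- setdiff(all_strata, unique(cells[[by]]))
  if (length(lost)) {
    warning("stratum/strata with no cells omitted: ",
      paste(lost, collapse = ", "),
      call. = FALSE
    )
  }
  keep_subtype <- "subtype" %in% names(cells) && by != "subtype"
  grp <- if (keep_subtype) c(by, "subtype") else by
  out <- cells |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), .data$phenotype,
      name = "n"
    ) |>
    dplyr::rename(cell_type = "phenotype") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(grp)),
      cell_type = types,
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      n_cells = sum(.data$n),
      percent = 100 * .data$n / .data$n_cells
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(compartment = compartment, .after = dplyr::all_of(grp))
  out
}

#' Pool all cells of each group into one composition
#'
#' Cell-weighted pooling: all cells from all samples of a group are
#' combined into a single composition before counting, so a 300-cell
#' sample carries three times the weight of a 100-cell sample (this is
#' not the mean of per-sample percentages).
#'
#' @param cells Phenotyped cell table.
#' @param group Grouping column, default `"subtype"`.
#' @inheritParams composition
#' @return A long composition tibble, one stratum per group.
#' @export
pool_compositions <- function(cells, group = "subtype",
                              compartment = c("all", "dermis", "epidermis"),
                              types = NULL) {
  composition(cells, by = group, compartment = match.arg(compartment),
    types = types
  )
}

#' Add derived total rows to a composition
#'
#' Appends `"Total T cells"` — the sum of the five T-lineage categories
#' (CD4+ T, CD8+ T, Treg, GranzymeB+, IL17A+) — and, when macrophage
#' categories are present, `"Total macrophages"` — the plain CD68+
#' category plus the M1/M2 polarization sub-fractions. The five T
#' lineages must all be present; a missing one is an error naming it.
#' Totals are derived rows: they do not enter the sum-to-100 category
#' set.
#'
#' @param comp Long composition tibble (columns `cell_type`, `percent`,
#'   any stratum metadata).
#' @return The tibble with total rows appended per stratum.
#' @export
derive_totals <- function(comp) {
  stopifnot(all(c("cell_type", "percent") %in% names(comp)))
  meta <- setdiff(names(comp), c("cell_type", "percent", "n"))
  totals <- comp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta))) |>
    dplyr::group_modify(function(d, key) {
      missing <- setdiff(T_LINEAGES, d$cell_type)
      if (length(missing)) {
        stop("cannot derive Total T cells; missing lineage(s): ",
          paste(missing, collapse = ", "),
          call. = FALSE
        )
      }
      rows <- tibble::tibble(
        cell_type = "Total T cells",
        percent = sum(d$percent[d$cell_type %in% T_LINEAGES])
      )
      macs <- intersect(c("macrophage", "M1", "M2"), d$cell_type)
      if ("macrophage" %in% macs) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          cell_type = "Total macrophages",
          percent = sum(d$percent[d$cell_type %in% macs])
        ))
      }
      if ("n" %in% names(d)) {
        rows$n <- c(
          sum(d$n[d$cell_type %in% T_LINEAGES]),
          if (nrow(rows) > 1) sum(d$n[d$cell_type %in% macs])
        )
      }
      rows
    }) |>
    dplyr::ungroup()
  dplyr::bind_rows(comp, totals)
}

#' Merge the compositions measured by two antibody panels
#'
#' Serial sections stained with different panels each resolve a subset
#' of the cell types: the T-cell panel sees the five T lineages, the
#' macrophage panel the macrophage/neutrophil categories, and both see
#' keratinocytes (PanCK) and an `"other"` rest class. The merge takes
#' each lineage from the panel that resolves it, averages keratinocyte
#' and `"other"` with cell-count weights (or `weights`), and
#' renormalizes to 100. Because each panel's `"other"` also contains
#' the cell types only the opposite panel can see, that mass is first
#' subtracted (using the opposite panel's estimate) so `"other"` means
#' the same rest class in both panels; without this correction the
#' merged lineage percentages would be biased low by the
#' renormalization.
#'
#' @param comp_tcell,comp_mac Long composition tibbles from the T-cell
#'   and macrophage panels, sharing their stratum metadata columns
#'   (e.g. `sample_id`, `subtype`, `compartment`).
#' @param weights Optional length-2 numeric (T-cell panel, macrophage
#'   panel) overriding the cell-count weights for the shared
#'   categories.
#' @return A merged long composition tibble whose exclusive categories
#'   sum to 100 per stratum.
#' @export
merge_panels <- function(comp_tcell, comp_mac, weights = NULL) {
  for (nm in c("cell_type", "percent")) {
    stopifnot(nm %in% names(comp_tcell), nm %in% names(comp_mac))
  }
  shared_cats <- c("keratinocyte", "other")
  clash <- setdiff(
    intersect(unique(comp_tcell$cell_type), unique(comp_mac$cell_type)),
    shared_cats
  )
  if (length(clash)) {
    stop("category claimed by both panels: ", paste(clash, collapse = ", "),
      call. = FALSE
    )
  }
  meta <- intersect(
    setdiff(names(comp_tcell), c("cell_type", "percent", "n", "n_cells")),
    setdiff(names(comp_mac), c("cell_type", "percent", "n", "n_cells"))
  )
  key_t <- split(
    seq_len(nrow(comp_tcell)),
    interaction(comp_tcell[meta], drop = TRUE, sep = "\r")
  )
  key_m <- split(
    seq_len(nrow(comp_mac)),
    interaction(comp_mac[meta], drop = TRUE, sep = "\r")
  )
  strata <- intersect(names(key_t), names(key_m))
  if (!length(strata)) stop("panels share no strata to merge", call. = FALSE)
  out <- lapply(strata, function(s) {
    dt <- comp_tcell[key_t[[s]], , drop = FALSE]
    dm <- comp_mac[key_m[[s]], , drop = FALSE]
    pt <- stats::setNames(dt$percent, dt$cell_type)
    pm <- stats::setNames(dm$percent, dm$cell_type)
    w <- weights
    if (is.null(w)) {
      w <- c(
        if ("n_cells" %in% names(dt)) dt$n_cells[1] else 1,
        if ("n_cells" %in% names(dm)) dm$n_cells[1] else 1
      )
    }
    w <- w / sum(w)
    t_cats <- intersect(T_LINEAGES, names(pt))
    m_cats <- intersect(MAC_CATEGORIES, names(pm))
    # each panel's "other" holds the opposite panel's exclusive mass
    other_t <- max(0, pt["other"] - sum(pm[m_cats]))
    other_m <- max(0, pm["other"] - sum(pt[t_cats]))
    merged <- c(
      pt[t_cats],
      pm[m_cats],
      keratinocyte = unname(
        w[1] * pt["keratinocyte"] + w[2] * pm["keratinocyte"]
      ),
      other = unname(w[1] * other_t + w[2] * other_m)
    )
    merged <- 100 * merged / sum(merged)
    res <- dt[rep(1, length(merged)), meta, drop = FALSE]
    res$cell_type <- names(merged)
    res$percent <- unname(merged)
    if ("n_cells" %in% names(dt) && "n_cells" %in% names(dm)) {
      res$n_cells <- dt$n_cells[1] + dm$n_cells[1]
    }
    res
  })
  dplyr::bind_rows(out)
}

#' Pivot a long composition to a samples-by-types matrix
#'
#' @param comp Long composition tibble.
#' @param id Column naming the rows (default `"sample_id"`).
#' @param value Column to spread (default `"percent"`).
#' @return Numeric matrix, rows = strata, columns = cell types.
#' @export
composition_matrix <- function(comp, id = "sample_id", value = "percent") {
  stopifnot(id %in% names(comp), value %in% names(comp))
  wide <- comp |>
    dplyr::select(dplyr::all_of(c(id, "cell_type", value))) |>
    tidyr::pivot_wider(
      names_from = "cell_type", values_from = dplyr::all_of(value)
    )
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[id]]
  m
}
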