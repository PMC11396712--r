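#' Configure a synthetic multiplex-IHC cohort
#'
#' Bundles everything [simulate_cell_table()] needs: the group structure,
#' per-group cell-type composition targets, the amount of inter-sample
#' variability (a Dirichlet concentration), the per-marker intensity
#' mixture models and the panel whose rules define each phenotype's
#' marker signature.
#'
#' Samples vary around their group target as
#' `Dirichlet(concentration * target)`; `dirichlet_concentration = Inf`
#' gives the degenerate limit where every sample's true composition is
#' the group target exactly. Keratinocytes are placed in the epidermis
#' with probability `keratinocyte_epidermis`, all other cell types with
#' probability `baseline_epidermis`.
#'
#' @param subtypes Character vector of group labels.
#' @param samples_per_subtype,cells_per_sample Positive integers.
#' @param composition_targets Named list, one named proportion vector
#'   per subtype over the panel's phenotype categories; each must sum
#'   to 1 (tolerance 1e-9). Defaults to [lp_composition_targets()]
#'   folded onto the panel's categories.
#' @param panel A [plex_panel()]; defaults to [tcell_panel()].
#' @param dirichlet_concentration Positive real (or `Inf`); default 200,
#'   which gives sample-to-sample scatter of a few percentage points on
#'   the dominant categories without degenerate zeros.
#' @param marker_models Named list of per-marker component models, see
#'   [default_marker_models()].
#' @param keratinocyte_epidermis,baseline_epidermis Probabilities that a
#'   keratinocyte / non-keratinocyte cell lies in the epidermis.
#' @param seed Integer seed; all randomness in the generator flows from
#'   it (global RNG state is untouched).
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(subtypes,
                          samples_per_subtype,
                          cells_per_sample,
                          composition_targets = NULL,
                          panel = tcell_panel(),
                          dirichlet_concentration = 200,
                          marker_models = default_marker_models(panel$markers),
                          keratinocyte_epidermis = 0.8,
                          baseline_epidermis = 0.2,
                          seed = 1) {
  stopifnot(inherits(panel, "plex_panel"))
  if (is.null(composition_targets)) {
    composition_targets <- lapply(
      lp_composition_targets()[subtypes],
      fold_targets_onto_panel,
      panel = panel
    )
  }
  cfg <- structure(
    list(
      subtypes = as.character(subtypes),
      samples_per_subtype = as.integer(samples_per_subtype),
      cells_per_sample = as.integer(cells_per_sample),
      composition_targets = composition_targets,
      panel = panel,
      dirichlet_concentration = dirichlet_concentration,
      marker_models = marker_models,
      keratinocyte_epidermis = keratinocyte_epidermis,
      baseline_epidermis = baseline_epidermis,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' Fold composition targets onto the categories one panel can resolve
#'
#' Cell types a panel cannot see (no rule for them) are real cells that
#' stain negative for every panel marker, so their mass moves into
#' `"other"` rather than being renormalized away.
#'
#' @param targets Named proportion vector.
#' @param panel A [plex_panel()].
#' @return Named proportion vector over `panel_phenotypes(panel)`.
#' @export
fold_targets_onto_panel <- function(targets, panel) {
  types <- panel_phenotypes(panel)
  visible <- intersect(names(targets), types)
  hidden <- setdiff(names(targets), types)
  out <- stats::setNames(numeric(length(types)), types)
  out[visible] <- targets[visible]
  out["other"] <- out["other"] + sum(targets[hidden])
  out
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    length(cfg$subtypes) >= 1,
    cfg$samples_per_subtype >= 1,
    cfg$cells_per_sample >= 1,
    cfg$dirichlet_concentration > 0
  )
  types <- panel_phenotypes(cfg$panel)
  missing_groups <- setdiff(cfg$subtypes, names(cfg$composition_targets))
  if (length(missing_groups)) {
    stop("no composition target for subtype(s): ",
      paste(missing_groups, collapse = ", "),
      call. = FALSE
    )
  }
  for (g in cfg$subtypes) {
    tg <- cfg$composition_targets[[g]]
    if (any(tg < 0)) stop("negative composition target in '", g, "'", call. = FALSE)
    if (abs(sum(tg) - 1) > 1e-9) {
      stop("composition targets for '", g, "' must sum to 1 (got ",
        format(sum(tg), digits = 12), ")",
        call. = FALSE
      )
    }
    bad <- setdiff(names(tg), types)
    if (length(bad)) {
      stop("composition target for '", g,
        "' references cell type(s) absent from the panel: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  missing_markers <- setdiff(cfg$panel$markers, names(cfg$marker_models))
  if (length(missing_markers)) {
    stop("no marker model for: ", paste(missing_markers, collapse = ", "),
      call. = FALSE
    )
  }
  for (mk in cfg$panel$markers) {
    mm <- cfg$marker_models[[mk]]
    if (!mm$family %in% c("normal", "lognormal", "weibull")) {
      stop("unknown family tag '", mm$family, "' for marker ", mk, call. = FALSE)
    }
    if (!(mm$pos_mean > mm$neg_mean)) {
      stop("pos_mean must exceed neg_mean for marker ", mk, call. = FALSE)
    }
  }
  cfg
}

# Draw one composition from Dirichlet(concentration * target); an Inf
# concentration is the degenerate point mass at the target, and zero
# target components stay exactly zero.
rdirichlet_one <- function(target, concentration) {
  if (is.infinite(concentration)) {
    return(target)
  }
  g <- numeric(length(target))
  pos <- target > 0
  g[pos] <- stats::rgamma(sum(pos), shape = concentration * target[pos])
  if (sum(g) == 0) g[pos] <- target[pos] # pathological underflow guard
  stats::setNames(g / sum(g), names(target))
}

draw_component <- function(n, family, m, s) {
  switch(family,
    normal = stats::rnorm(n, m, s),
    lognormal = {
      p <- lnorm_from_moments(m, s)
      stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])
    },
    weibull = {
      p <- weibull_from_moments(m, s)
      stats::rweibull(n, p[["shape"]], p[["scale"]])
    },
    stop("unknown family tag: ", family, call. = FALSE)
  )
}

#' Simulate a per-cell marker intensity table with known ground truth
#'
#' Generates the table a segmentation pipeline would export from one
#' stained panel (one row per cell; sample, subtype, panel, tissue
#' compartment and one mean-intensity column per marker), together with
#' full ground truth: each cell's true phenotype and marker positivity,
#' and each sample's true (Dirichlet-drawn) composition.
#'
#' Each cell's true phenotype is drawn from its sample's true
#' composition; the phenotype's rule in `config$panel` dictates which
#' markers are truly positive; intensities come from the positive or
#' negative component of the marker's configured family accordingly.
#' The same seed always reproduces the identical table.
#'
#' @param config A [cohort_config()].
#' @param composition_draws Optional tibble (`sample_id`, `subtype`,
#'   `cell_type`, `proportion`) fixing each sample's true composition
#'   instead of drawing it — used by [simulate_two_panel_cohort()] so
#'   serial sections stained with different panels share one truth.
#'   Cell types missing from the panel are folded into `"other"`.
#' @return A list of class `plex_cohort` with elements `cells` (tibble:
#'   `sample_id`, `subtype`, `panel`, `compartment`, `cell_id`, one
#'   numeric column per marker), `truth` (list with `cells` — true
#'   phenotype and per-marker logical positivity — and `composition` —
#'   true per-sample proportions), and `config`.
#' @export
simulate_cell_table <- function(config, composition_draws = NULL) {
  config <- validate_cohort_config(config)
  panel <- config$panel
  markers <- panel$markers
  signatures <- c(
    lapply(panel$rules, `[[`, "requires"),
    list(character(0))
  )
  names(signatures) <- panel_phenotypes(panel)

  with_seed(config$seed, {
    cell_rows <- list()
    truth_rows <- list()
    comp_rows <- list()
    for (g in config$subtypes) {
      target <- config$composition_targets[[g]]
      for (j in seq_len(config$samples_per_subtype)) {
        sid <- sprintf("%s_s%d", gsub("\\s+", "-", g), j)
        props <- if (is.null(composition_draws)) {
          rdirichlet_one(target, config$dirichlet_concentration)
        } else {
          d <- composition_draws[composition_draws$sample_id == sid, ]
          if (!nrow(d)) {
            stop("no composition draw for sample ", sid, call. = FALSE)
          }
          fold_targets_onto_panel(
            stats::setNames(d$proportion, d$cell_type), panel
          )
        }
        n <- config$cells_per_sample
        types <- sample(names(props), n, replace = TRUE, prob = props)
        is_ker <- types == "keratinocyte"
        p_epi <- ifelse(is_ker, config$keratinocyte_epidermis,
          config$baseline_epidermis
        )
        compartment <- ifelse(stats::runif(n) < p_epi, "epidermis", "dermis")
        pos_mat <- vapply(
          markers,
          function(mk) {
            vapply(signatures[types], function(sg) mk %in% sg, logical(1))
          },
          logical(n)
        )
        intens <- matrix(NA_real_, n, length(markers),
          dimnames = list(NULL, markers)
        )
        for (mk in markers) {
          mm <- config$marker_models[[mk]]
          pos <- pos_mat[, mk]
          x <- draw_component(n, mm$family, mm$neg_mean, mm$neg_sd)
          if (any(pos)) {
            x[pos] <- draw_component(sum(pos), mm$family, mm$pos_mean, mm$pos_sd)
          }
          intens[, mk] <- x
        }
        cell_id <- sprintf("%s_c%05d", sid, seq_len(n))
        cell_rows[[sid]] <- dplyr::bind_cols(
          tibble::tibble(
            sample_id = sid, subtype = g, panel = panel$name,
            compartment = compartment, cell_id = cell_id
          ),
          tibble::as_tibble(intens)
        )
        truth_rows[[sid]] <- dplyr::bind_cols(
          tibble::tibble(
            cell_id = cell_id, sample_id = sid, subtype = g,
            true_type = types
          ),
          tibble::as_tibble(pos_mat)
        )
        comp_rows[[sid]] <- tibble::tibble(
          sample_id = sid, subtype = g,
          cell_type = names(props), proportion = unname(props)
        )
      }
    }
    structure(
      list(
        cells = dplyr::bind_rows(cell_rows),
        truth = list(
          cells = dplyr::bind_rows(truth_rows),
          composition = dplyr::bind_rows(comp_rows)
        ),
        config = config
      ),
      class = "plex_cohort"
    )
  })
}

#' Simulate serial sections stained with both antibody panels
#'
#' Draws one true composition per sample over the full cell-type set
#' (the union both panels resolve), then generates an independent cell
#' table per panel from that shared truth — emulating serial sections
#' of the same tissue block stained with the T-cell and macrophage
#' panels. This is the input [merge_panels()] is designed to
#' reconstitute.
#'
#' @param subtypes,samples_per_subtype,cells_per_sample As in
#'   [cohort_config()] (`cells_per_sample` applies to each panel).
#' @param composition_targets Named list of per-subtype proportion
#'   vectors over the full category set; default
#'   [lp_composition_targets()].
#' @param dirichlet_concentration,marker_models_args Passed through;
#'   `marker_models_args` is a list of arguments for
#'   [default_marker_models()].
#' @param treg_requires_cd4 Passed to [tcell_panel()].
#' @param seed Integer seed (the composition draw and both panels'
#'   cells all derive from it).
#' @return A list with `tcell` and `macrophage` (`plex_cohort` objects
#'   sharing `truth$composition`) and `truth_composition` (the shared
#'   per-sample draws over the full category set).
#' @export
simulate_two_panel_cohort <- function(subtypes, samples_per_subtype,
                                      cells_per_sample,
                                      composition_targets =
                                        lp_composition_targets(),
                                      dirichlet_concentration = 200,
                                      marker_models_args = list(),
                                      treg_requires_cd4 = FALSE,
                                      seed = 1) {
  missing_groups <- setdiff(subtypes, names(composition_targets))
  if (length(missing_groups)) {
    stop("no composition target for subtype(s): ",
      paste(missing_groups, collapse = ", "),
      call. = FALSE
    )
  }
  draws <- with_seed(seed, {
    purrr::map_dfr(subtypes, function(g) {
      purrr::map_dfr(seq_len(samples_per_subtype), function(j) {
        props <- rdirichlet_one(
          composition_targets[[g]], dirichlet_concentration
        )
        tibble::tibble(
          sample_id = sprintf("%s_s%d", gsub("\\s+", "-", g), j),
          subtype = g, cell_type = names(props), proportion = unname(props)
        )
      })
    })
  })
  panels <- list(
    tcell = tcell_panel(treg_requires_cd4 = treg_requires_cd4),
    macrophage = macrophage_panel()
  )
  out <- lapply(seq_along(panels), function(i) {
    p <- panels[[i]]
    cfg <- cohort_config(
      subtypes, samples_per_subtype, cells_per_sample,
      composition_targets = lapply(
        composition_targets[subtypes], fold_targets_onto_panel, panel = p
      ),
      panel = p,
      dirichlet_concentration = dirichlet_concentration,
      marker_models = do.call(
        default_marker_models, c(list(markers = p$markers),
          marker_models_args
        )
      ),
      seed = seed + i
    )
    simulate_cell_table(cfg, composition_draws = draws)
  })
  names(out) <- names(panels)
  out$truth_composition <- draws
  out
}

#' @export
print.plex_cohort <- function(x, ...) {
  cat("<plex_cohort> panel '", x$config$panel$name, "': ",
    nrow(x$cells), " cells, ",
    length(unique(x$cells$sample_id)), " samples, ",
    length(x$config$subtypes), " subtypes\n",
    sep = ""
  )
  invisible(x)
}

#' Write a cell table (or any tibble) as TSV
#'
#' Plain tab-separated export with a header and no quoting or row
#' names, so identical inputs give byte-identical files.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Simulate a gene-by-sample count matrix with planted fold changes
#'
#' Negative-binomial counts for a targeted expression panel: gene
#' baseline means are log-normal across genes, a set of housekeeping
#' genes is constrained to a log2 fold change of zero, and selected
#' genes carry planted log2 fold changes applied to every non-reference
#' group (the reference is the first unique value of `groups`).
#'
#' @param n_genes Total number of genes (including housekeeping).
#' @param n_housekeeping Number of housekeeping genes (`< n_genes`).
#' @param groups Character vector, one group label per sample.
#' @param planted_log2fc Named numeric vector, gene -> log2 fold change.
#'   Naming a housekeeping gene is an error. Genes are `"gene001"`...;
#'   housekeeping genes are `"HK01"`...
#' @param nb_dispersion Negative-binomial dispersion (`size = 1/disp`);
#'   must be positive.
#' @param seed Integer seed.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-gene
#'   baseline means.
#' @return A list of class `plex_counts`: `counts` (tibble with `gene`,
#'   `housekeeping`, one integer column per sample) and `truth` (tibble
#'   `gene`, `log2fc`).
#' @export
simulate_count_matrix <- function(n_genes, n_housekeeping, groups,
                                  planted_log2fc = NULL,
                                  nb_dispersion = 0.1, seed = 1,
                                  base_meanlog = log(300), base_sdlog = 1) {
  stopifnot(
    n_housekeeping >= 1, n_housekeeping < n_genes,
    nb_dispersion > 0, length(groups) >= 2
  )
  groups <- as.character(groups)
  n_reg <- n_genes - n_housekeeping
  genes <- c(
    sprintf("gene%03d", seq_len(n_reg)),
    sprintf("HK%02d", seq_len(n_housekeeping))
  )
  hk <- c(rep(FALSE, n_reg), rep(TRUE, n_housekeeping))
  lfc <- stats::setNames(numeric(n_genes), genes)
  if (!is.null(planted_log2fc)) {
    bad <- setdiff(names(planted_log2fc), genes)
    if (length(bad)) {
      stop("planted fold change for unknown gene(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    on_hk <- intersect(names(planted_log2fc), genes[hk])
    if (length(on_hk)) {
      stop("planted fold change assigned to housekeeping gene(s): ",
        paste(on_hk, collapse = ", "),
        call. = FALSE
      )
    }
    lfc[names(planted_log2fc)] <- planted_log2fc
  }
  ref <- groups[1]
  sample_ids <- paste0(groups, "_", stats::ave(seq_along(groups), groups,
    FUN = seq_along
  ))
  with_seed(seed, {
    base_mu <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
    counts <- matrix(0L, n_genes, length(groups),
      dimnames = list(genes, sample_ids)
    )
    for (s in seq_along(groups)) {
      mu <- if (groups[s] == ref) base_mu else base_mu * 2^lfc
      counts[, s] <- stats::rnbinom(n_genes, mu = mu, size = 1 / nb_dispersion)
    }
    structure(
      list(
        counts = dplyr::bind_cols(
          tibble::tibble(gene = genes, housekeeping = hk),
          tibble::as_tibble(counts)
        ),
        truth = tibble::tibble(gene = genes, log2fc = unname(lfc)),
        groups = stats::setNames(groups, sample_ids)
      ),
      class = "plex_counts"
    )
  })
}
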