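# End-to-end orchestration: simulate -> register -> density -> coproject
# -> stats, with a single seed, stage toggles and machine-readable output.

#' Pipeline configuration
#'
#' Bundles the analysis parameters (defaults: 30 μm density bins, 50 μm
#' match radius, 90% core polygon, 256 Otsu levels), the simulated study
#' design, the seed, and stage toggles.
#'
#' @param regions regions simulated per mouse (reference first; default a
#'   motor-cortex four-color design).
#' @param n_mice simulated mice (default 3).
#' @param n_slices_per_rc slices per rostrocaudal level (default 2).
#' @param coproj_sets named multi-target set probabilities passed to
#'   [default_coprojection()]; default: probability 0.04 on each
#'   consecutive region pair.
#' @param contra_fraction probability a neuron is contralateral
#'   (default 0.05).
#' @param bin_size_um,match_radius_um,keep_fraction,otsu_levels analysis
#'   parameters.
#' @param seed integer seed for all randomness.
#' @param stages character subset of
#'   `c("simulate", "register", "density", "coproject", "stats")`.
#' @param out_dir optional output directory for tabular artifacts.
#' @param cells,detections optional observed data (skip simulation; then
#'   drop `"simulate"` from `stages`).
#' @param connectivity optional symmetrized connectivity table.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(regions = c("iRSP", "MOs", "ALM", "MOp"),
                            n_mice = 3, n_slices_per_rc = 2,
                            coproj_sets = NULL, contra_fraction = 0.05,
                            bin_size_um = 30, match_radius_um = 50,
                            keep_fraction = 0.9, otsu_levels = 256,
                            seed = 1,
                            stages = c("simulate", "register", "density",
                                       "coproject", "stats"),
                            out_dir = NULL, cells = NULL, detections = NULL,
                            connectivity = NULL) {
  stopifnot(bin_size_um > 0, match_radius_um > 0, otsu_levels > 1,
            keep_fraction > 0, keep_fraction < 1)
  regions <- canonical_region(regions)
  if (is.null(coproj_sets) && length(regions) >= 2) {
    pairs <- mapply(function(a, b) label_string(c(a, b)),
                    regions[-length(regions)], regions[-1])
    coproj_sets <- setNames(rep(0.04, length(pairs)), pairs)
  }
  structure(list(regions = regions, n_mice = n_mice,
                 n_slices_per_rc = n_slices_per_rc,
                 coproj_sets = coproj_sets,
                 contra_fraction = contra_fraction,
                 bin_size_um = bin_size_um,
                 match_radius_um = match_radius_um,
                 keep_fraction = keep_fraction, otsu_levels = otsu_levels,
                 seed = seed, stages = stages, out_dir = out_dir,
                 cells = cells, detections = detections,
                 connectivity = connectivity),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$coproj_sets)) y$coproj_sets <- unlist(y$coproj_sets)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: `simulate` (or user-supplied tables)
#' produces cells and detections; `register` aligns slices to the
#' reference pathway and assigns zones; `density` computes per-pathway
#' density maps, Otsu module masks, pairwise spatial overlap, core/shell
#' proportions and contra/ipsi ratios; `coproject` resolves co-labeling
#' and tabulates labeling patterns; `stats` assembles the pair-association
#' table and grand-mean correlations. Disabling a stage that a later
#' enabled stage depends on is an error. Given a fixed seed, the result is
#' fully deterministic.
#'
#' @param config a [pipeline_config()].
#' @return report bundle (list): `cells`, `registered`, `proportions`,
#'   `contra_ipsi`, `maps`, `overlaps`, `patterns`, `jaccard`,
#'   `associations`, `correlations`, `log`.
#' @export
run_pipeline <- function(config) {
  st <- config$stages
  deps <- list(register = "simulate", density = "register",
               coproject = "register", stats = c("density", "coproject"))
  have_data <- !is.null(config$cells)
  for (s in st) for (d in deps[[s]]) {
    if (!(d %in% st) && !(d == "simulate" && have_data))
      stop("stage '", s, "' requires stage '", d, "'")
  }
  bundle <- list(log = list(seed = config$seed,
                            parameters = config[c("bin_size_um",
                                                  "match_radius_um",
                                                  "keep_fraction",
                                                  "otsu_levels")]))
  ref <- config$regions[1]

  if ("simulate" %in% st) {
    pw <- default_pathways(config$regions)
    cp <- default_coprojection(pw, coproj_sets = config$coproj_sets)
    designs <- rep(list(list(pathways = pw, coproj = cp,
                             n_slices_per_rc = config$n_slices_per_rc,
                             reference = ref,
                             contra_fraction = config$contra_fraction,
                             keep_fraction = config$keep_fraction)),
                   config$n_mice)
    names(designs) <- sprintf("sim%02d", seq_len(config$n_mice))
    sim <- generate_study(designs, seed = config$seed)
    bundle$cells <- sim$cells; bundle$detections <- sim$detections
    bundle$truth <- sim$truth
  } else {
    bundle$cells <- config$cells; bundle$detections <- config$detections
  }

  if ("register" %in% st) {
    cl <- classify_cells(bundle$cells, ref_channel = ref,
                         keep_fraction = config$keep_fraction)
    bundle$registered <- cl$cells
    bundle$frames <- cl$frames
  }

  if ("density" %in% st) {
    reg <- bundle$registered
    bundle$maps <- pathway_density_maps(reg, config$bin_size_um,
                                        config$otsu_levels)
    chs <- names(bundle$maps)
    ov <- list()
    for (p in if (length(chs) >= 2) combn(chs, 2, simplify = FALSE) else list())
      ov[[length(ov) + 1L]] <- data.frame(
        region_a = p[1], region_b = p[2],
        spatial_overlap = spatial_overlap(bundle$maps[[p[1]]]$mask,
                                          bundle$maps[[p[2]]]$mask),
        stringsAsFactors = FALSE)
    bundle$overlaps <- do.call(rbind, ov)
    bundle$proportions <- core_shell_proportions(reg)
    bundle$contra_ipsi <- contra_ipsi_ratio(bundle$cells)
    bundle$histograms <- axis_histograms(reg, config$bin_size_um)
  }

  if ("coproject" %in% st) {
    pats <- list(); jac <- list()
    for (m in unique(bundle$detections$mouse_id)) {
      det <- bundle$detections[bundle$detections$mouse_id == m &
                               bundle$detections$hemisphere == "ipsi", ]
      resolved <- resolve_colabels(det, config$match_radius_um)
      u <- uncorrected_counts(resolved, channels = config$regions)
      ie <- suppressWarnings(inclusion_exclusion(u))
      pats[[m]] <- list(uncorrected = u, exact = ie$exact,
                        union_count = ie$union_count)
      jm <- pairwise_jaccard(u)
      for (p in combn(rownames(jm), 2, simplify = FALSE))
        jac[[length(jac) + 1L]] <- data.frame(
          mouse_id = m, region_a = p[1], region_b = p[2],
          coprojection_rate = jm[p[1], p[2]], stringsAsFactors = FALSE)
    }
    bundle$patterns <- pats
    bundle$jaccard <- do.call(rbind, jac)
  }

  if ("stats" %in% st) {
    assoc <- pair_associations(
      data.frame(region_a = bundle$jaccard$region_a,
                 region_b = bundle$jaccard$region_b,
                 mouse_id = bundle$jaccard$mouse_id,
                 coprojection_rate = bundle$jaccard$coprojection_rate),
      overlaps = bundle$overlaps, connectivity = config$connectivity)
    bundle$associations <- assoc
    key <- paste(assoc$region_a, assoc$region_b, sep = "|")
    corrs <- list(
      overlap = try(correlate_grand_means(key, assoc$spatial_overlap,
                                          assoc$coprojection_rate),
                    silent = TRUE),
      distance = try(correlate_grand_means(key, assoc$injection_distance_mm,
                                           assoc$coprojection_rate),
                     silent = TRUE))
    if (!is.null(assoc$connectivity) && !all(is.na(assoc$connectivity))) {
      ok <- !is.na(assoc$connectivity)
      corrs$connectivity <- try(
        correlate_grand_means(key[ok], assoc$connectivity[ok],
                              assoc$coprojection_rate[ok]), silent = TRUE)
    }
    bundle$correlations <- lapply(corrs, function(x)
      if (inherits(x, "try-error")) NULL else x)
  }

  if (!is.null(config$out_dir)) write_bundle(bundle, config)
  bundle
}

# write tabular artifacts; header comments record the parameters used
write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf(
    "# clamap seed=%s bin_size_um=%g match_radius_um=%g keep_fraction=%g otsu_levels=%d",
    config$seed, config$bin_size_um, config$match_radius_um,
    config$keep_fraction, config$otsu_levels)
  put <- function(df, file) {
    path <- file.path(config$out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                                 row.names = FALSE, quote = FALSE))
  }
  if (!is.null(bundle$cells)) write_cell_table(bundle$cells,
    file.path(config$out_dir, "cells.csv"))
  if (!is.null(bundle$registered)) write_cell_table(bundle$registered,
    file.path(config$out_dir, "registered.csv"))
  if (!is.null(bundle$proportions)) put(bundle$proportions, "proportions.csv")
  if (!is.null(bundle$contra_ipsi)) put(bundle$contra_ipsi, "contra_ipsi.csv")
  if (!is.null(bundle$overlaps)) put(bundle$overlaps, "overlaps.csv")
  if (!is.null(bundle$jaccard)) put(bundle$jaccard, "jaccard.csv")
  if (!is.null(bundle$associations)) put(bundle$associations,
                                         "associations.csv")
  summary <- list(
    seed = config$seed, parameters = bundle$log$parameters,
    n_cells = if (!is.null(bundle$cells)) nrow(bundle$cells) else NULL,
    union_counts = if (!is.null(bundle$patterns))
      lapply(bundle$patterns, `[[`, "union_count") else NULL,
    correlations = if (!is.null(bundle$correlations))
      lapply(bundle$correlations, function(x) x$r) else NULL)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
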