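# Domain vocabulary, cell tables, experiment metadata, connectivity tables.

RC_LEVELS <- c("rostral", "intermediate", "caudal")
HEMISPHERES <- c("ipsi", "contra")
CELL_CLASSES <- c("projection", "PV", "SST", "NPY")
TRACERS <- c("FB", "CTB647", "rAAV2-GFP", "rAAV2-tdTomato")

# canonical spellings: rostral/caudal retrosplenial appear under two names
REGION_SYNONYMS <- c(aRSP = "rRSP", pRSP = "cRSP")

#' Canonicalize cortical region names
#'
#' The rostral and caudal retrosplenial cortex appear in the literature
#' under two spellings each (rRSP/aRSP, cRSP/pRSP); both are accepted and
#' mapped to a single canonical token (`rRSP`, `cRSP`).
#'
#' @param region character vector of region names.
#' @return character vector of canonical names.
#' @export
#' @examples
#' canonical_region(c("aRSP", "iRSP", "pRSP"))
canonical_region <- function(region) {
  out <- as.character(region)
  hit <- out %in% names(REGION_SYNONYMS)
  out[hit] <- REGION_SYNONYMS[out[hit]]
  names(out) <- names(region)
  out
}

#' Cortical injection-region catalog
#'
#' The 14 cortical regions injected across all experiments, with their
#' stereotaxic injection coordinates (AP/ML in mm from bregma, DV in mm
#' from brain surface) and the tracers used at each site.
#'
#' @return data.frame with columns `region`, `ap_mm`, `ml_mm`, `dv_mm`,
#'   `tracers` (semicolon-joined).
#' @export
#' @examples
#' nrow(region_catalog())  # 14
region_catalog <- function() {
  path <- system.file("extdata", "region_catalog.csv", package = "clamap")
  cat <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(cat$region))
  cat
}

#' Core/shell zone fractions and neuron counts per pathway
#'
#' Per-pathway mean per-slice neuron counts and the percentage of neurons
#' in the dorsal shell, core and ventral shell, at each rostrocaudal level.
#' Used to parameterize the synthetic-data generator.
#'
#' @return data.frame with columns `region`, `rc_level`, `count_mean`,
#'   `count_sd`, `dorsal_pct`, `core_pct`, `ventral_pct`.
#' @export
zone_fraction_table <- function() {
  path <- system.file("extdata", "zone_fractions.csv", package = "clamap")
  z <- read.csv(path, stringsAsFactors = FALSE)
  z$rc_level <- factor(z$rc_level, levels = RC_LEVELS)
  z
}

#' Multicolor labeling-pattern counts for all tracing experiments
#'
#' Uncorrected labeling-pattern counts for each multicolor experiment:
#' channels A (fast blue), B (CTB-647), C (rAAV2-GFP), D (rAAV2-tdTomato)
#' map to the cortical regions in columns `region_A` ... `region_D`; the
#' pattern columns `A` ... `ABCD` count neurons labeled by every channel in
#' the pattern (a triple-labeled neuron contributes to seven patterns).
#' `NA` regions mark off-target injections whose channel was not analyzed.
#'
#' @return data.frame, one row per mouse.
#' @export
multicolor_counts <- function() {
  path <- system.file("extdata", "multicolor_counts.csv", package = "clamap")
  read.csv(path, stringsAsFactors = FALSE,
           na.strings = c("NA", ""), check.names = FALSE)
}

## ---- cell tables -----------------------------------------------------------

CELL_COLUMNS <- c("cell_id", "mouse_id", "slice_id", "rc_level", "hemisphere",
                  "x_um", "y_um", "labels")

#' Validate a cell-record table
#'
#' A cell table has one row per labeled neuron with columns `cell_id`,
#' `mouse_id`, `slice_id`, `rc_level` (rostral/intermediate/caudal),
#' `hemisphere` (ipsi/contra), `x_um` (mediolateral, positive lateral),
#' `y_um` (dorsoventral, positive dorsal), `labels` (semicolon-joined
#' channel tokens, non-empty) and optionally `cell_class`
#' (projection/PV/SST/NPY) plus columns added downstream (`zone`).
#'
#' @param cells data.frame.
#' @param channels optional character vector of declared channels; if given,
#'   every label must be one of them.
#' @return the validated data.frame, invisibly unchanged.
#' @export
validate_cells <- function(cells, channels = NULL) {
  missing_cols <- setdiff(CELL_COLUMNS, names(cells))
  if (length(missing_cols) > 0)
    stop("cell table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_rc <- which(!cells$rc_level %in% RC_LEVELS)
  if (length(bad_rc) > 0)
    stop("unknown rc_level '", cells$rc_level[bad_rc[1]],
         "' at row ", bad_rc[1])
  bad_h <- which(!cells$hemisphere %in% HEMISPHERES)
  if (length(bad_h) > 0)
    stop("unknown hemisphere '", cells$hemisphere[bad_h[1]],
         "' at row ", bad_h[1])
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um)))
    stop("non-finite coordinates in cell table")
  labs <- label_list(cells)
  if (any(lengths(labs) == 0) || any(!nzchar(unlist(labs))))
    stop("every cell must carry a non-empty label set")
  if (!is.null(channels)) {
    unknown <- setdiff(unique(unlist(labs)), channels)
    if (length(unknown) > 0)
      stop("labels not among declared channels: ",
           paste(unknown, collapse = ", "))
  }
  if ("cell_class" %in% names(cells)) {
    bad <- !is.na(cells$cell_class) & !cells$cell_class %in% CELL_CLASSES
    if (any(bad))
      stop("unknown cell_class at row ", which(bad)[1])
  }
  invisible(cells)
}

#' Split the semicolon-joined label column into a list of channel sets
#' @param cells cell table.
#' @return list of character vectors, one per row.
#' @export
label_list <- function(cells) {
  strsplit(as.character(cells$labels), ";", fixed = TRUE)
}

#' Does each cell carry a given channel label?
#' @param cells cell table.
#' @param channel single channel token.
#' @return logical vector.
#' @export
has_channel <- function(cells, channel) {
  vapply(label_list(cells), function(s) channel %in% s, logical(1))
}

#' Canonical label-set string: sorted, semicolon-joined channel tokens
#' @param channels character vector of channel tokens.
#' @return single string.
#' @export
label_string <- function(channels) {
  paste(sort(unique(as.character(channels)), method = "radix"),
        collapse = ";")
}

#' Read a cell-record table from delimited text
#'
#' Accepts comma- or tab-delimited files with a header row declaring the
#' column dialect of [validate_cells()].
#'
#' @param path file path.
#' @param channels optional declared channel set for label validation.
#' @return validated cell data.frame, row order preserved.
#' @export
read_cell_table <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  cells <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (col in c("cell_id", "mouse_id", "slice_id", "labels"))
    if (col %in% names(cells)) cells[[col]] <- as.character(cells[[col]])
  validate_cells(cells, channels)
  cells
}

#' Write a cell-record table in canonical form
#'
#' Canonical formatting: comma-delimited, mandatory columns first,
#' coordinates fixed to three decimals (nanometre resolution), no quoting.
#' `write_cell_table` composed with [read_cell_table()] is the identity on
#' canonical files.
#'
#' @param cells validated cell table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  validate_cells(cells)
  extra <- setdiff(names(cells), CELL_COLUMNS)
  out <- cells[, c(CELL_COLUMNS, extra), drop = FALSE]
  out$x_um <- sprintf("%.3f", out$x_um)
  out$y_um <- sprintf("%.3f", out$y_um)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- experiment metadata ---------------------------------------------------

#' Construct tracing-experiment metadata
#'
#' Describes one multicolor experiment: which imaging channel carries which
#' tracer injected into which cortical region.
#'
#' @param mouse_id identifier.
#' @param channels named list, `channel -> list(tracer, region)`; 2 to 4
#'   channels, regions pairwise distinct, tracers from
#'   FB/CTB647/rAAV2-GFP/rAAV2-tdTomato.
#' @param off_target character vector of channels excluded from analysis
#'   (injection missed its target); must be a proper subset of channels.
#' @param sex optional.
#' @return object of class `tracing_experiment`.
#' @export
#' @examples
#' tracing_experiment("M1", list(
#'   A = list(tracer = "FB", region = "PL"),
#'   B = list(tracer = "CTB647", region = "iRSP")))
tracing_experiment <- function(mouse_id, channels, off_target = character(),
                               sex = NA_character_) {
  if (length(channels) < 2 || length(channels) > 4)
    stop("an experiment uses 2-4 channels")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  regions <- canonical_region(vapply(channels, `[[`, "", "region"))
  if (anyDuplicated(regions))
    stop("mapped regions must be pairwise distinct")
  tracers <- vapply(channels, `[[`, "", "tracer")
  if (!all(tracers %in% TRACERS))
    stop("unknown tracer: ", paste(setdiff(tracers, TRACERS), collapse = ", "))
  if (!all(off_target %in% names(channels)) ||
      length(off_target) >= length(channels))
    stop("off_target must be a proper subset of the declared channels")
  for (ch in names(channels)) channels[[ch]]$region <- regions[[ch]]
  structure(list(mouse_id = as.character(mouse_id), sex = sex,
                 channels = channels, off_target = off_target),
            class = "tracing_experiment")
}

#' Channels of an experiment that are analyzed (not off target)
#' @param exp `tracing_experiment`.
#' @return character vector of channel tokens.
#' @export
analyzed_channels <- function(exp) {
  setdiff(names(exp$channels), exp$off_target)
}

#' Region injected for a given channel
#' @param exp `tracing_experiment`.
#' @param channel channel token(s).
#' @return character vector of region names.
#' @export
channel_region <- function(exp, channel) {
  vapply(channel, function(ch) exp$channels[[ch]]$region, "")
}

#' @export
print.tracing_experiment <- function(x, ...) {
  cat("Tracing experiment", x$mouse_id, "\n")
  for (ch in names(x$channels)) {
    flag <- if (ch %in% x$off_target) " [off target]" else ""
    cat(sprintf("  %s: %s -> %s%s\n", ch, x$channels[[ch]]$tracer,
                x$channels[[ch]]$region, flag))
  }
  invisible(x)
}

#' Read experiment metadata from a YAML config
#'
#' Expected structure: `mouse_id`, optional `sex`, optional `off_target`
#' (list), and `channels`, a map from channel token to `{tracer, region}`.
#'
#' @param path YAML file path.
#' @return `tracing_experiment` (or list of them if the file holds a
#'   top-level `experiments` list).
#' @export
read_experiment <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(e)
    tracing_experiment(e$mouse_id, e$channels,
                       off_target = as.character(e$off_target %||% character()),
                       sex = e$sex %||% NA_character_)
  if (!is.null(y$experiments)) lapply(y$experiments, build) else build(y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Experiments corresponding to the packaged multicolor count table
#'
#' Reconstructs `tracing_experiment` metadata for each mouse of the
#' packaged multicolor experiment table ([multicolor_counts()]); channels
#' whose region is `NA` there are marked off target.
#'
#' @return named list of `tracing_experiment` objects.
#' @export
packaged_experiments <- function() {
  tab <- multicolor_counts()
  tracer_of <- c(A = "FB", B = "CTB647", C = "rAAV2-GFP",
                 D = "rAAV2-tdTomato")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    chans <- list(); off <- character()
    for (ch in c("A", "B", "C", "D")) {
      reg <- row[[paste0("region_", ch)]]
      if (is.na(reg)) next
      chans[[ch]] <- list(tracer = tracer_of[[ch]], region = reg)
    }
    tracing_experiment(row$mouse_id, chans, off_target = off, sex = row$sex)
  })
  names(out) <- tab$mouse_id
  out
}

## ---- connectivity tables ---------------------------------------------------

#' Read a directed region-pair connectivity table
#'
#' Delimited text with columns `source`, `target`, `strength` (adjusted
#' anterograde projection intensity, non-negative). Duplicate ordered pairs
#' are ambiguous and rejected.
#'
#' @param path file path.
#' @return data.frame of directed entries with canonical region names.
#' @export
read_connectivity <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("source", "target", "strength")
  if (!all(need %in% names(tab)))
    stop("connectivity table needs columns: ", paste(need, collapse = ", "))
  tab$source <- canonical_region(tab$source)
  tab$target <- canonical_region(tab$target)
  if (any(tab$strength < 0))
    stop("negative connectivity strength at row ", which(tab$strength < 0)[1])
  key <- paste(tab$source, tab$target, sep = "->")
  if (anyDuplicated(key))
    stop("duplicate ordered pair: ", key[duplicated(key)][1])
  tab
}

#' Symmetrize a directed connectivity table
#'
#' The two directions of each region pair are averaged into a single
#' undirected strength; a pair observed in only one direction keeps that
#' sole observation.
#'
#' @param directed data.frame with `source`, `target`, `strength`.
#' @return data.frame with `region_a`, `region_b` (sorted within pair) and
#'   `strength`.
#' @export
#' @examples
#' d <- data.frame(source = c("X", "Y"), target = c("Y", "X"),
#'                 strength = c(2, 4))
#' symmetrize_connectivity(d)$strength  # 3
symmetrize_connectivity <- function(directed) {
  a <- pmin(directed$source, directed$target)
  b <- pmax(directed$source, directed$target)
  key <- paste(a, b, sep = "|")
  agg <- tapply(directed$strength, key, mean)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  data.frame(region_a = vapply(parts, `[`, "", 1),
             region_b = vapply(parts, `[`, "", 2),
             strength = as.numeric(agg), row.names = NULL)
}

#' Look up the symmetrized strength of a region pair
#' @param conn output of [symmetrize_connectivity()].
#' @param region_a,region_b region names.
#' @return numeric strength, `NA` if absent.
#' @export
connectivity_strength <- function(conn, region_a, region_b) {
  region_a <- canonical_region(region_a); region_b <- canonical_region(region_b)
  a <- pmin(region_a, region_b); b <- pmax(region_a, region_b)
  idx <- match(paste(a, b), paste(conn$region_a, conn$region_b))
  conn$strength[idx]
}
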