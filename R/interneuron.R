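# Density, ratio, overlap, and spatial-profile statistics for PV/SST/NPY
# interneurons relative to the core/shell frame. Interneuron cells reuse
# the cell-table machinery with `cell_class` set, so registration and
# zoning apply unchanged.

#' Cell density per unit area
#' @param count cells counted in the ROI.
#' @param area_mm2 ROI area in mm^2 (> 0).
#' @return cells per mm^2.
#' @export
area_density <- function(count, area_mm2) {
  if (any(area_mm2 <= 0)) stop("area must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  count / area_mm2
}

#' Normalize core/shell neuropil fluorescence
#'
#' Neuropil intensities are in arbitrary per-slice units, so core and
#' shell values of a marker are normalized within slice: by the maximum of
#' the two ROI intensities (default) or by their sum.
#'
#' @param core_value,shell_value mean ROI intensities (>= 0, not both 0).
#' @param norm `"max"` (default) or `"sum"`.
#' @return named numeric: `core`, `shell`, each in \[0, 1\].
#' @export
normalized_neuropil <- function(core_value, shell_value,
                                norm = c("max", "sum")) {
  norm <- match.arg(norm)
  if (core_value < 0 || shell_value < 0) stop("intensities must be >= 0")
  den <- if (norm == "max") max(core_value, shell_value)
         else core_value + shell_value
  if (den == 0) stop("both intensities zero: normalization undefined")
  c(core = core_value / den, shell = shell_value / den)
}

#' Overlap between two interneuron subtypes
#'
#' Fraction of double-labeled cells among all cells of either marker;
#' identical, input for input, to the co-projection rate
#' ([jaccard_rate()]).
#'
#' @inheritParams jaccard_rate
#' @return fraction in \[0, 1\].
#' @export
subtype_overlap <- function(count_a, count_b, count_ab) {
  jaccard_rate(count_a, count_b, count_ab)
}

#' Correlation between two binned spatial profiles
#'
#' Pearson correlation between equal-length binned (dorsoventral or
#' mediolateral) density profiles, e.g. an interneuron marker against the
#' reference pathway.
#'
#' @param profile_a,profile_b numeric vectors of equal length.
#' @return correlation coefficient.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b))
    stop("profiles must have equal length")
  if (sd(profile_a) == 0 || sd(profile_b) == 0)
    stop("constant profile: correlation undefined")
  cor(profile_a, profile_b)
}

#' Summarize an ROI measurement table
#'
#' Per-ROI cell densities and interneuron ratios from a table with one row
#' per (slice, ROI, cell class) measurement.
#'
#' @param roi data.frame with columns `slice_id`, `roi`, `cell_class`,
#'   `count`, `area_mm2`.
#' @return list with `density` (per-row cells/mm^2 added) and `ratios`
#'   (per slice and ROI: SST:PV and NPY:PV density ratios where both
#'   classes were measured).
#' @export
roi_summary <- function(roi) {
  need <- c("slice_id", "roi", "cell_class", "count", "area_mm2")
  if (!all(need %in% names(roi)))
    stop("ROI table needs columns: ", paste(need, collapse = ", "))
  roi$density_mm2 <- area_density(roi$count, roi$area_mm2)
  key <- paste(roi$slice_id, roi$roi)
  rows <- list()
  for (k in unique(key)) {
    sub <- roi[key == k, ]
    d <- setNames(sub$density_mm2, sub$cell_class)
    if (!"PV" %in% names(d) || d[["PV"]] == 0) next
    rows[[k]] <- data.frame(
      slice_id = sub$slice_id[1], roi = sub$roi[1],
      sst_pv = if ("SST" %in% names(d)) d[["SST"]] / d[["PV"]] else NA_real_,
      npy_pv = if ("NPY" %in% names(d)) d[["NPY"]] / d[["PV"]] else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(density = roi,
       ratios = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
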