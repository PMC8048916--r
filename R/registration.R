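# Per-slice registration to the reference pathway and core/shell zoning.
#
# Every slice is aligned independently: coordinates are (optionally)
# rotated so the dorsoventral axis is vertical, then translated so the
# centroid of the reference-channel neurons sits at the origin. The
# claustrum core is the convex hull of the closest 90% of reference
# neurons to that centroid; neurons outside the hull are dorsal or ventral
# shell by the sign of their registered y coordinate.

#' Rotate the cells of one slice about a center
#'
#' Rigid rotation (counter-clockwise, degrees) of all cell coordinates in a
#' slice; pairwise distances are preserved. By default the rotation center
#' is the centroid of all cells in the slice.
#'
#' @param cells cell table, all rows sharing one `slice_id`.
#' @param angle_deg rotation angle in degrees.
#' @param center length-2 numeric `(x, y)`; default the slice centroid.
#' @return cell table with rotated `x_um`, `y_um`.
#' @export
rotate_cells <- function(cells, angle_deg, center = NULL) {
  if (length(unique(cells$slice_id)) > 1)
    stop("rotate_cells operates on a single slice")
  if (is.null(center)) center <- c(mean(cells$x_um), mean(cells$y_um))
  th <- angle_deg * pi / 180
  dx <- cells$x_um - center[1]; dy <- cells$y_um - center[2]
  cells$x_um <- center[1] + cos(th) * dx - sin(th) * dy
  cells$y_um <- center[2] + sin(th) * dx + cos(th) * dy
  cells
}

# angle (deg) rotating the first principal axis of (x, y) onto the y axis
principal_vertical_angle <- function(x, y) {
  pc <- prcomp(cbind(x, y))
  v <- pc$rotation[, 1]
  (90 - atan2(v[2], v[1]) * 180 / pi) %% 180
}

#' Register the cells of every slice to the reference population
#'
#' For each slice with at least `min_ref` reference-channel neurons:
#' optionally rotate so the dorsoventral axis is vertical (angle from
#' slice metadata when supplied, otherwise estimated so the first
#' principal axis of the reference population is vertical), then translate
#' so the reference centroid is the origin. Slices with fewer than
#' `min_ref` reference neurons are dropped with a warning.
#'
#' @param cells cell table (any number of slices, ipsi and contra; the
#'   reference frame of a slice is computed from its ipsilateral reference
#'   neurons).
#' @param ref_channel channel token of the reference pathway.
#' @param rotation `"none"` (default; the acquisition already aligned the
#'   dorsoventral axis), `"auto"` (principal-axis estimate), or a named
#'   numeric vector of angles per `slice_id`.
#' @param min_ref minimum reference neurons per slice (default 3).
#' @return list with `cells` (registered table, same columns) and `frames`
#'   (data.frame: `slice_id`, `centroid_x_um`, `centroid_y_um`,
#'   `rotation_deg`, `n_ref`).
#' @export
register_to_reference <- function(cells, ref_channel, rotation = "none",
                                  min_ref = 3) {
  validate_cells(cells)
  slices <- unique(cells$slice_id)
  out <- list(); frames <- list(); skipped <- character()
  for (s in slices) {
    sl <- cells[cells$slice_id == s, , drop = FALSE]
    is_ref <- has_channel(sl, ref_channel) & sl$hemisphere == "ipsi"
    if (sum(is_ref) < min_ref) { skipped <- c(skipped, s); next }
    ang <- 0
    if (identical(rotation, "auto")) {
      ang <- principal_vertical_angle(sl$x_um[is_ref], sl$y_um[is_ref])
    } else if (is.numeric(rotation)) {
      ang <- if (!is.null(names(rotation))) rotation[[s]] else rotation
    }
    if (ang != 0) sl <- rotate_cells(sl, ang,
                                     center = c(mean(sl$x_um[is_ref]),
                                                mean(sl$y_um[is_ref])))
    cx <- mean(sl$x_um[is_ref]); cy <- mean(sl$y_um[is_ref])
    sl$x_um <- sl$x_um - cx
    sl$y_um <- sl$y_um - cy
    out[[s]] <- sl
    frames[[s]] <- data.frame(slice_id = s, centroid_x_um = cx,
                              centroid_y_um = cy, rotation_deg = ang,
                              n_ref = sum(is_ref))
  }
  if (length(skipped) > 0)
    warning("skipped slice(s) with < ", min_ref, " reference neurons: ",
            paste(skipped, collapse = ", "))
  if (length(out) == 0)
    stop("no slice had >= ", min_ref, " reference-channel neurons")
  list(cells = do.call(rbind, c(out, list(make.row.names = FALSE))),
       frames = do.call(rbind, c(frames, list(make.row.names = FALSE))))
}

#' Core polygon from registered reference points
#'
#' Ranks reference points by Euclidean distance to the origin (the
#' reference centroid), keeps the closest `ceil(keep_fraction * n)`, and
#' takes their convex hull as the claustrum core. Ties in the distance
#' ranking are broken by `cell_id` order when ids are supplied. Because
#' retained points all lie within the radius of the furthest retained
#' point, every removed point falls strictly outside the hull.
#'
#' @param ref_points two-column matrix or data.frame of registered
#'   reference coordinates (μm).
#' @param keep_fraction fraction of reference neurons defining the core
#'   (default 0.9).
#' @param cell_id optional ids for deterministic tie-breaking.
#' @return object of class `core_polygon`: list with `vertices`
#'   (counter-clockwise matrix), `keep_fraction`, `n_ref`, `n_kept`,
#'   `radius_um` (distance of the furthest retained point).
#' @export
core_polygon <- function(ref_points, keep_fraction = 0.9, cell_id = NULL) {
  pts <- as.matrix(ref_points)[, 1:2, drop = FALSE]
  n <- nrow(pts)
  if (n < 3) stop("need >= 3 reference points to form a polygon")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  d <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  ord <- if (is.null(cell_id)) order(d) else order(d, cell_id)
  m <- ceiling(keep_fraction * n)
  kept <- pts[ord[seq_len(m)], , drop = FALSE]
  hull <- chull(kept[, 1], kept[, 2])
  if (length(hull) < 3)
    stop("degenerate geometry: retained reference points are collinear")
  structure(list(vertices = kept[rev(hull), , drop = FALSE],  # ccw
                 keep_fraction = keep_fraction, n_ref = n, n_kept = m,
                 radius_um = max(d[ord[seq_len(m)]])),
            class = "core_polygon")
}

#' @export
print.core_polygon <- function(x, ...) {
  cat(sprintf("Core polygon: %d/%d reference neurons (keep %.0f%%), %d vertices, radius %.1f um\n",
              x$n_kept, x$n_ref, 100 * x$keep_fraction,
              nrow(x$vertices), x$radius_um))
  invisible(x)
}

#' Classify registered points into core / dorsal shell / ventral shell
#'
#' A point inside or on the core polygon is `core`; outside the polygon it
#' is `dorsal_shell` when its registered y coordinate is at or above the
#' reference centroid (y >= 0) and `ventral_shell` otherwise. Total
#' function: every point receives exactly one zone.
#'
#' @param points two-column matrix/data.frame of registered coordinates.
#' @param polygon a [core_polygon()].
#' @return factor with levels `core`, `dorsal_shell`, `ventral_shell`.
#' @export
classify_zone <- function(points, polygon) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  inside <- pracma::inpolygon(pts[, 1], pts[, 2],
                              polygon$vertices[, 1], polygon$vertices[, 2],
                              boundary = TRUE)
  zone <- ifelse(inside, "core",
                 ifelse(pts[, 2] >= 0, "dorsal_shell", "ventral_shell"))
  factor(zone, levels = c("core", "dorsal_shell", "ventral_shell"))
}

#' Register, build per-slice core polygons, and assign zones
#'
#' Convenience wrapper running [register_to_reference()] and, per slice,
#' [core_polygon()] on the ipsilateral reference neurons followed by
#' [classify_zone()] on every neuron of the slice.
#'
#' @inheritParams register_to_reference
#' @param keep_fraction core polygon fraction (default 0.9).
#' @return list with `cells` (registered table plus `zone` column),
#'   `frames`, and `polygons` (named list of `core_polygon` per slice).
#' @export
classify_cells <- function(cells, ref_channel, keep_fraction = 0.9,
                           rotation = "none", min_ref = 3) {
  reg <- register_to_reference(cells, ref_channel, rotation, min_ref)
  cl <- reg$cells
  cl$zone <- factor(NA, levels = c("core", "dorsal_shell", "ventral_shell"))
  polys <- list()
  for (s in unique(cl$slice_id)) {
    idx <- cl$slice_id == s
    sl <- cl[idx, , drop = FALSE]
    is_ref <- has_channel(sl, ref_channel) & sl$hemisphere == "ipsi"
    poly <- core_polygon(cbind(sl$x_um[is_ref], sl$y_um[is_ref]),
                         keep_fraction, cell_id = sl$cell_id[is_ref])
    polys[[s]] <- poly
    cl$zone[idx] <- classify_zone(cbind(sl$x_um, sl$y_um), poly)
  }
  list(cells = cl, frames = reg$frames, polygons = polys)
}
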