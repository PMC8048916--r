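# Binned spatial density maps, Otsu module boundaries, overlap metrics,
# axis histograms, core/shell proportion tables, contra/ipsi ratios.

#' Binned 2D spatial density map
#'
#' Counts registered points on a grid of `bin_size_um` square bins whose
#' edges are integer multiples of `bin_size_um` from the origin (the
#' reference centroid). Bins are half-open `[edge, edge + bin)`, so a
#' point exactly on an interior edge belongs to the higher-coordinate bin.
#' The extent is the bounding box of the points, padded by one bin, unless
#' supplied.
#'
#' @param x,y registered coordinates (μm).
#' @param bin_size_um bin side (default 30).
#' @param extent optional `c(xmin, xmax, ymin, ymax)` in μm (snapped
#'   outward to bin edges).
#' @return object of class `density_map`: list with `counts` (matrix,
#'   rows = x bins, cols = y bins), `x_edges`, `y_edges` (lower edges),
#'   `bin_size_um`, `n_total`, `n_in_extent`.
#' @export
density_map <- function(x, y, bin_size_um = 30, extent = NULL) {
  if (bin_size_um <= 0) stop("bin size must be > 0")
  if (length(x) < 1) stop("need at least one point")
  if (is.null(extent)) {
    extent <- c(min(x) - bin_size_um, max(x) + bin_size_um,
                min(y) - bin_size_um, max(y) + bin_size_um)
  }
  lo <- floor(extent[c(1, 3)] / bin_size_um)
  hi <- ceiling(extent[c(2, 4)] / bin_size_um)
  x_edges <- seq(lo[1], hi[1] - 1) * bin_size_um
  y_edges <- seq(lo[2], hi[2] - 1) * bin_size_um
  ix <- floor(x / bin_size_um) - lo[1] + 1
  iy <- floor(y / bin_size_um) - lo[2] + 1
  ok <- ix >= 1 & ix <= length(x_edges) & iy >= 1 & iy <= length(y_edges)
  counts <- matrix(0L, length(x_edges), length(y_edges))
  if (any(ok)) {
    tab <- table(factor(ix[ok], levels = seq_along(x_edges)),
                 factor(iy[ok], levels = seq_along(y_edges)))
    counts <- matrix(as.integer(tab), length(x_edges), length(y_edges))
  }
  structure(list(counts = counts, x_edges = x_edges, y_edges = y_edges,
                 bin_size_um = bin_size_um, n_total = length(x),
                 n_in_extent = sum(ok)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map: %d x %d bins of %g um, %d/%d points in extent\n",
              nrow(x$counts), ncol(x$counts), x$bin_size_um,
              x$n_in_extent, x$n_total))
  invisible(x)
}

#' Otsu threshold of a set of density values
#'
#' Classic histogram thresholding: values are binned into `n_levels`
#' equal-width levels and the split maximizing the between-class variance
#' (equivalently minimizing the within-class variance) is chosen. The
#' returned threshold is the upper edge of the last background level, so
#' the foreground is `value >= threshold`.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_levels histogram resolution (default 256).
#' @return numeric threshold.
#' @export
otsu_threshold <- function(values, n_levels = 256) {
  v <- values[is.finite(values)]
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant map: no threshold separates two classes")
  width <- diff(rng) / n_levels
  lev <- pmin(floor((v - rng[1]) / width), n_levels - 1)  # 0-based level
  h <- tabulate(lev + 1L, nbins = n_levels)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_levels) - 0.5) * width
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_levels]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-n_levels])  # split after level k
  rng[1] + k * width
}

#' Otsu module boundary of a density map
#'
#' Thresholds the map's bin values with [otsu_threshold()]; the module
#' mask is `density >= threshold`. Empty bins inside the extent take part
#' in the histogram.
#'
#' @param map a [density_map()] (or any object with a `counts` matrix).
#' @param n_levels histogram resolution (default 256).
#' @return object of class `module_mask`: list with `mask` (logical
#'   matrix aligned to the map grid), `threshold`, `x_edges`, `y_edges`,
#'   `bin_size_um`.
#' @export
otsu_boundary <- function(map, n_levels = 256) {
  vals <- as.numeric(map$counts)
  thr <- otsu_threshold(vals, n_levels)
  structure(list(mask = map$counts >= thr, threshold = thr,
                 x_edges = map$x_edges, y_edges = map$y_edges,
                 bin_size_um = map$bin_size_um),
            class = "module_mask")
}

#' Spatial overlap between two module masks
#'
#' The area jointly occupied by both modules divided by the sum of the two
#' individual module areas, in bins: `|A n B| / (|A| + |B|)`. Ranges 0
#' (disjoint) to 0.5 (identical); this is deliberately not a Jaccard of
#' areas.
#'
#' @param mask_a,mask_b [otsu_boundary()] masks on identical grids (or
#'   plain logical matrices of equal dimension).
#' @return overlap fraction in \[0, 0.5\].
#' @export
spatial_overlap <- function(mask_a, mask_b) {
  a <- if (is.list(mask_a)) mask_a$mask else mask_a
  b <- if (is.list(mask_b)) mask_b$mask else mask_b
  if (!all(dim(a) == dim(b))) stop("masks are on different grids")
  if (is.list(mask_a) && is.list(mask_b) &&
      (!isTRUE(all.equal(mask_a$x_edges, mask_b$x_edges)) ||
       !isTRUE(all.equal(mask_a$y_edges, mask_b$y_edges))))
    stop("masks are on different grids")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("both masks are empty: overlap undefined")
  sum(a & b) / (na + nb)
}

#' Per-pathway average density maps with module masks
#'
#' For each channel, per-slice density maps on a common grid are averaged
#' across the slices of each mouse, then across mice, normalized to peak
#' one, and thresholded with Otsu's method. Ipsilateral cells only.
#'
#' @param cells registered cell table.
#' @param bin_size_um bin side (default 30).
#' @param n_levels Otsu histogram resolution (default 256).
#' @param channels channels to map (default: all observed).
#' @return named list per channel: list with `map` (average
#'   `density_map`, peak-normalized) and `mask` ([otsu_boundary()]).
#' @export
pathway_density_maps <- function(cells, bin_size_um = 30, n_levels = 256,
                                 channels = NULL) {
  cells <- cells[cells$hemisphere == "ipsi", , drop = FALSE]
  if (is.null(channels))
    channels <- sort(unique(unlist(label_list(cells))))
  extent <- c(min(cells$x_um) - bin_size_um, max(cells$x_um) + bin_size_um,
              min(cells$y_um) - bin_size_um, max(cells$y_um) + bin_size_um)
  out <- list()
  for (ch in channels) {
    sub <- cells[has_channel(cells, ch), , drop = FALSE]
    if (nrow(sub) == 0) next
    mouse_means <- list()
    for (m in unique(sub$mouse_id)) {
      ms <- sub[sub$mouse_id == m, , drop = FALSE]
      slice_maps <- lapply(unique(ms$slice_id), function(s) {
        sl <- ms[ms$slice_id == s, , drop = FALSE]
        density_map(sl$x_um, sl$y_um, bin_size_um, extent)$counts
      })
      mouse_means[[m]] <- Reduce(`+`, slice_maps) / length(slice_maps)
    }
    avg <- Reduce(`+`, mouse_means) / length(mouse_means)
    if (max(avg) > 0) avg <- avg / max(avg)
    proto <- density_map(sub$x_um[1], sub$y_um[1], bin_size_um, extent)
    proto$counts <- avg
    proto$n_total <- nrow(sub); proto$n_in_extent <- NA_integer_
    out[[ch]] <- list(map = proto, mask = otsu_boundary(proto, n_levels))
  }
  out
}

#' Normalized axis histograms per pathway
#'
#' Distribution of each pathway's ipsilateral neurons over dorsoventral
#' bins, mediolateral bins, and rostrocaudal level. Histograms are
#' normalized to sum to one; empty pathways are dropped with a warning.
#'
#' @param cells registered cell table.
#' @param bin_size_um spatial bin side (default 30).
#' @param channels channels (default: all observed).
#' @return named list per channel with numeric vectors `dv`, `ml` (named
#'   by lower bin edge) and `rc` (named by level).
#' @export
axis_histograms <- function(cells, bin_size_um = 30, channels = NULL) {
  cells <- cells[cells$hemisphere == "ipsi", , drop = FALSE]
  if (is.null(channels))
    channels <- sort(unique(unlist(label_list(cells))))
  norm_hist <- function(v) {
    idx <- floor(v / bin_size_um)
    tab <- table(idx)
    h <- as.numeric(tab) / length(v)
    names(h) <- as.numeric(names(tab)) * bin_size_um
    h
  }
  out <- list()
  for (ch in channels) {
    sub <- cells[has_channel(cells, ch), , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("pathway '", ch, "' has no cells; excluded")
      next
    }
    rc <- table(factor(sub$rc_level, levels = RC_LEVELS)) / nrow(sub)
    out[[ch]] <- list(dv = norm_hist(sub$y_um), ml = norm_hist(sub$x_um),
                      rc = setNames(as.numeric(rc), RC_LEVELS))
  }
  out
}

#' Core / shell proportions per pathway and rostrocaudal level
#'
#' Percentage of each pathway's ipsilateral neurons in the dorsal shell,
#' core and ventral shell at each rostrocaudal level (rows sum to 100),
#' with the mean and SD of per-slice counts. Neurons with several labels
#' contribute to every labeled pathway (uncorrected convention).
#'
#' @param cells registered cell table with a `zone` column
#'   (see [classify_cells()]).
#' @return data.frame with columns `channel`, `rc_level`, `dorsal_pct`,
#'   `core_pct`, `ventral_pct`, `n`, `count_mean`, `count_sd`.
#' @export
core_shell_proportions <- function(cells) {
  if (!"zone" %in% names(cells)) stop("cells need a 'zone' column")
  cells <- cells[cells$hemisphere == "ipsi", , drop = FALSE]
  channels <- sort(unique(unlist(label_list(cells))))
  rows <- list()
  for (ch in channels) {
    sub <- cells[has_channel(cells, ch), , drop = FALSE]
    for (rc in RC_LEVELS) {
      s <- sub[sub$rc_level == rc, , drop = FALSE]
      if (nrow(s) == 0) next
      tab <- table(factor(s$zone, levels = c("dorsal_shell", "core",
                                             "ventral_shell")))
      per_slice <- as.numeric(table(s$slice_id))
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, rc_level = rc,
        dorsal_pct = 100 * tab[["dorsal_shell"]] / nrow(s),
        core_pct = 100 * tab[["core"]] / nrow(s),
        ventral_pct = 100 * tab[["ventral_shell"]] / nrow(s),
        n = nrow(s), count_mean = mean(per_slice),
        count_sd = if (length(per_slice) > 1) sd(per_slice) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Contralateral / ipsilateral labeling ratio
#'
#' Ratio of contralateral to ipsilateral neuron counts per mouse and
#' pathway, pooled over slices within mouse. Undefined (reported `NA`)
#' when a mouse/pathway has no ipsilateral neurons.
#'
#' @param cells cell table (both hemispheres).
#' @return data.frame `mouse_id`, `channel`, `n_contra`, `n_ipsi`,
#'   `ratio`.
#' @export
contra_ipsi_ratio <- function(cells) {
  channels <- sort(unique(unlist(label_list(cells))))
  rows <- list()
  for (m in unique(cells$mouse_id)) {
    mc <- cells[cells$mouse_id == m, , drop = FALSE]
    for (ch in channels) {
      sub <- mc[has_channel(mc, ch), , drop = FALSE]
      n_ipsi <- sum(sub$hemisphere == "ipsi")
      n_contra <- sum(sub$hemisphere == "contra")
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = m, channel = ch, n_contra = n_contra, n_ipsi = n_ipsi,
        ratio = if (n_ipsi > 0) n_contra / n_ipsi else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
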