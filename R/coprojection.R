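# Cross-channel co-label matching, labeling-pattern resolution,
# co-projection statistics, and tracer-detectability estimation.

#' Match co-labeled detections across channels within one slice
#'
#' For every unordered channel pair, candidate cross-channel detection
#' pairs within `radius_um` are matched one-to-one greedily by ascending
#' distance (ties broken lexicographically by the two cell ids); leftover
#' detections stay unmatched.
#'
#' @param detections cell table of one slice, one row per detection with a
#'   single-channel `labels` entry.
#' @param radius_um matching radius (default 50).
#' @return data.frame with `cell_i`, `cell_j`, `channel_i`, `channel_j`,
#'   `distance_um`, sorted by ascending distance.
#' @export
match_colabels <- function(detections, radius_um = 50) {
  if (length(unique(detections$slice_id)) > 1)
    stop("match_colabels operates on a single slice")
  chans <- vapply(label_list(detections), function(s) s[1], "")
  uch <- sort(unique(chans))
  out <- list()
  for (pair in if (length(uch) >= 2) combn(uch, 2, simplify = FALSE) else list()) {
    i_idx <- which(chans == pair[1]); j_idx <- which(chans == pair[2])
    if (length(i_idx) == 0 || length(j_idx) == 0) next
    dx <- outer(detections$x_um[i_idx], detections$x_um[j_idx], "-")
    dy <- outer(detections$y_um[i_idx], detections$y_um[j_idx], "-")
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= radius_um, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    ids_i <- detections$cell_id[i_idx[cand[, 1]]]
    ids_j <- detections$cell_id[j_idx[cand[, 2]]]
    dist <- d[cand]
    ord <- order(dist, ids_i, ids_j)
    used_i <- character(); used_j <- character()
    for (k in ord) {
      if (ids_i[k] %in% used_i || ids_j[k] %in% used_j) next
      used_i <- c(used_i, ids_i[k]); used_j <- c(used_j, ids_j[k])
      out[[length(out) + 1L]] <- data.frame(
        cell_i = ids_i[k], cell_j = ids_j[k],
        channel_i = pair[1], channel_j = pair[2],
        distance_um = dist[k], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(cell_i = character(), cell_j = character(),
                      channel_i = character(), channel_j = character(),
                      distance_um = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$distance_um, res$cell_i, res$cell_j), , drop = FALSE]
}

#' Assemble matched detections into resolved multi-label neurons
#'
#' Connected components of the match graph (detections as nodes, matched
#' pairs as edges) become single neurons whose label set is the union of
#' the member channels. Edges are applied in ascending distance order; an
#' edge that would merge two detections of the same channel into one
#' component is discarded.
#'
#' @param matches output of [match_colabels()].
#' @param detections the slice's detection table.
#' @return resolved cell table: one row per neuron, `labels` the union
#'   set, coordinates the mean over member detections, `cell_id` the
#'   lexicographically first member id.
#' @export
assemble_label_sets <- function(matches, detections) {
  ids <- detections$cell_id
  chans <- vapply(label_list(detections), function(s) s[1], "")
  parent <- seq_along(ids)
  comp_chans <- lapply(chans, identity)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(matches) > 0) {
    ord <- order(matches$distance_um, matches$cell_i, matches$cell_j)
    for (k in ord) {
      a <- find(match(matches$cell_i[k], ids))
      b <- find(match(matches$cell_j[k], ids))
      if (a == b) next
      if (length(intersect(comp_chans[[a]], comp_chans[[b]])) > 0) next
      parent[b] <- a
      comp_chans[[a]] <- union(comp_chans[[a]], comp_chans[[b]])
    }
  }
  root <- vapply(seq_along(ids), find, 0L)
  rows <- lapply(split(seq_along(ids), root), function(members) {
    sub <- detections[members, , drop = FALSE]
    first <- which.min(rank(sub$cell_id))
    data.frame(cell_id = min(sub$cell_id), mouse_id = sub$mouse_id[first],
               slice_id = sub$slice_id[first], rc_level = sub$rc_level[first],
               hemisphere = sub$hemisphere[first],
               x_um = mean(sub$x_um), y_um = mean(sub$y_um),
               labels = label_string(unlist(label_list(sub))),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  res[order(res$cell_id), , drop = FALSE]
}

#' Resolve per-channel detections into multi-label neurons, slice by slice
#'
#' @param detections detection table (any number of slices).
#' @param radius_um matching radius (default 50).
#' @return resolved cell table over all slices.
#' @export
resolve_colabels <- function(detections, radius_um = 50) {
  parts <- lapply(unique(detections$slice_id), function(s) {
    sl <- detections[detections$slice_id == s, , drop = FALSE]
    assemble_label_sets(match_colabels(sl, radius_um), sl)
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

## ---- labeling patterns -----------------------------------------------------

#' Number of possible labeling patterns for k channels
#'
#' A neuron labeled by any non-empty subset of k tracers: `2^k - 1`
#' patterns (15 for four-color tracing).
#'
#' @param k channel count (>= 1).
#' @return integer.
#' @export
enumerate_patterns <- function(k) {
  if (k < 1) stop("k must be >= 1")
  2L^as.integer(k) - 1L
}

#' All non-empty channel subsets, as canonical pattern names
#' @param channels character vector of channel tokens.
#' @return character vector of `2^k - 1` pattern names, by size then
#'   alphabetically.
#' @export
all_patterns <- function(channels) {
  channels <- sort(unique(channels))
  pats <- unlist(lapply(seq_along(channels), function(sz)
    combn(channels, sz, FUN = label_string)))
  pats
}

#' Uncorrected pattern counts from a collection of label sets
#'
#' A neuron is counted under every non-empty subset of its label set (the
#' convention of the packaged experiment table: a neuron labeled A and B
#' contributes to the A, B, and AB counts).
#'
#' @param labels character vector of label-set strings (semicolon-joined)
#'   or a cell table.
#' @param channels channel vocabulary (default: all observed).
#' @return named integer vector over [all_patterns()].
#' @export
uncorrected_counts <- function(labels, channels = NULL) {
  if (is.data.frame(labels)) labels <- labels$labels
  sets <- strsplit(as.character(labels), ";", fixed = TRUE)
  if (is.null(channels)) channels <- sort(unique(unlist(sets)))
  pats <- all_patterns(channels)
  pat_sets <- strsplit(pats, ";", fixed = TRUE)
  counts <- vapply(pat_sets, function(S)
    sum(vapply(sets, function(L) all(S %in% L), logical(1))), 0L)
  setNames(counts, pats)
}

#' Exact pattern counts from a collection of label sets
#' @inheritParams uncorrected_counts
#' @return named integer vector over [all_patterns()]: neurons whose label
#'   set equals each pattern exactly.
#' @export
exact_counts <- function(labels, channels = NULL) {
  if (is.data.frame(labels)) labels <- labels$labels
  canon <- vapply(strsplit(as.character(labels), ";", fixed = TRUE),
                  label_string, "")
  if (is.null(channels)) channels <- sort(unique(unlist(strsplit(canon, ";"))))
  pats <- all_patterns(channels)
  tab <- table(factor(canon, levels = pats))
  setNames(as.integer(tab), pats)
}

#' Convert uncorrected pattern counts to exact counts (inclusion-exclusion)
#'
#' Moebius inversion over the subset lattice:
#' `exact(S) = sum over T >= S of (-1)^(|T|-|S|) uncorrected(T)`; the
#' number of distinct neurons is the sum of the exact counts. Real count
#' tables can be slightly inconsistent (manual counting of overlapping
#' patterns), yielding small negative exact counts; by default these
#' trigger a warning, with `strict = TRUE` an error naming the pattern.
#'
#' @param uncorrected named numeric vector over patterns (names as
#'   produced by [all_patterns()]).
#' @param strict error (rather than warn) on negative exact counts.
#' @return list with `exact` (named vector) and `union_count`.
#' @export
inclusion_exclusion <- function(uncorrected, strict = FALSE) {
  pats <- names(uncorrected)
  if (is.null(pats)) stop("uncorrected counts must be named by pattern")
  sets <- strsplit(pats, ";", fixed = TRUE)
  exact <- vapply(seq_along(pats), function(i) {
    S <- sets[[i]]
    sum(vapply(seq_along(pats), function(j) {
      Tt <- sets[[j]]
      if (all(S %in% Tt))
        (-1)^(length(Tt) - length(S)) * uncorrected[[j]]
      else 0
    }, 0))
  }, 0)
  names(exact) <- pats
  neg <- which(exact < 0)
  if (length(neg) > 0) {
    msg <- paste0("inconsistent uncorrected counts: negative exact count for ",
                  paste(pats[neg], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  list(exact = exact, union_count = sum(exact))
}

#' Uncorrected pattern counts of a packaged multicolor experiment
#'
#' Extracts one mouse's row of [multicolor_counts()] as a named pattern
#' vector over its analyzed channels (off-target channels dropped),
#' pattern names in canonical semicolon form.
#'
#' @param mouse_id mouse identifier (e.g. `"M58"`).
#' @return named numeric vector of uncorrected counts.
#' @export
packaged_uncorrected <- function(mouse_id) {
  tab <- multicolor_counts()
  row <- tab[tab$mouse_id == mouse_id, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown mouse: ", mouse_id)
  chans <- c("A", "B", "C", "D")
  chans <- chans[!is.na(unlist(row[paste0("region_", chans)]))]
  pats <- all_patterns(chans)
  cols <- vapply(strsplit(pats, ";"), paste, "", collapse = "")
  counts <- as.numeric(row[1, cols])
  names(counts) <- pats
  if (anyNA(counts[!grepl(";", pats)]))
    stop("missing single-channel count in mouse ", mouse_id)
  counts[!is.na(counts)]  # some mice lack higher-order pattern counts
}

#' Pairwise co-projection (Jaccard) rate from labeling counts
#'
#' Proportion of neurons projecting to both of two regions:
#' `AB / (A + B - AB)` with A, B the (uncorrected) single-channel counts
#' and AB the double-labeled count.
#'
#' @param count_a,count_b neurons labeled by each channel.
#' @param count_ab neurons labeled by both (`<= min(count_a, count_b)`).
#' @return rate in \[0, 1\].
#' @export
#' @examples
#' jaccard_rate(482, 434, 131)  # ~0.167
jaccard_rate <- function(count_a, count_b, count_ab) {
  if (any(c(count_a, count_b, count_ab) < 0)) stop("counts must be >= 0")
  if (count_ab > min(count_a, count_b))
    stop("double-labeled count exceeds a single-channel count")
  den <- count_a + count_b - count_ab
  if (den == 0) stop("no labeled neurons: rate undefined")
  count_ab / den
}

#' Pairwise co-projection matrix from uncorrected counts
#' @param uncorrected named pattern-count vector.
#' @return symmetric matrix of [jaccard_rate()] values over single
#'   channels, `NA` where a pair count is unavailable.
#' @export
pairwise_jaccard <- function(uncorrected) {
  singles <- names(uncorrected)[!grepl(";", names(uncorrected))]
  k <- length(singles)
  m <- matrix(NA_real_, k, k, dimnames = list(singles, singles))
  diag(m) <- 1
  for (pair in combn(singles, 2, simplify = FALSE)) {
    key <- label_string(pair)
    if (!key %in% names(uncorrected)) next
    m[pair[1], pair[2]] <- m[pair[2], pair[1]] <-
      jaccard_rate(uncorrected[[pair[1]]], uncorrected[[pair[2]]],
                   uncorrected[[key]])
  }
  m
}

#' Fraction of neurons projecting to at least `min_labels` targets
#'
#' @param exact named exact pattern-count vector (see
#'   [inclusion_exclusion()]).
#' @param min_labels minimum label-set size.
#' @return fraction of distinct neurons.
#' @export
multi_target_fraction <- function(exact, min_labels) {
  union_count <- sum(exact)
  if (union_count == 0) stop("no neurons: fraction undefined")
  sizes <- lengths(strsplit(names(exact), ";", fixed = TRUE))
  sum(exact[sizes >= min_labels]) / union_count
}

#' Tracer detection probabilities by capture-recapture
#'
#' Co-injection of two tracers at one site marks the same projection
#' population twice; Lincoln-Petersen estimates each tracer's detection
#' probability from the single- and double-labeled counts:
#' `p_a = both / (both + b_only)`, `p_b = both / (both + a_only)`. The
#' observable co-projection ceiling for the pair is
#' `p_a p_b / (p_a + p_b - p_a p_b)`.
#'
#' @param a_only,b_only neurons labeled by one tracer only.
#' @param both double-labeled neurons (> 0).
#' @return list with `p_a`, `p_b`, `max_observable_jaccard`.
#' @export
#' @examples
#' detection_probability(30, 30, 70)  # p = 0.7, ceiling ~0.538
detection_probability <- function(a_only, b_only, both) {
  if (any(c(a_only, b_only, both) < 0)) stop("counts must be >= 0")
  if (both == 0) stop("no double-labeled neurons: detection inestimable")
  p_a <- both / (both + b_only)
  p_b <- both / (both + a_only)
  list(p_a = p_a, p_b = p_b,
       max_observable_jaccard = p_a * p_b / (p_a + p_b - p_a * p_b))
}
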