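# Relating co-projection rates to module overlap, injection-site distance
# and corticocortical connectivity; shared statistical tests.

#' Euclidean distance between cortical injection sites
#'
#' Distance over the stereotaxic (AP, ML, DV) injection coordinates of the
#' packaged catalog, in mm. `dims = 2` restricts to the AP/ML plane.
#'
#' @param region_a,region_b region names.
#' @param catalog region catalog (default [region_catalog()]).
#' @param dims 3 (default) or 2.
#' @return distance in mm.
#' @export
#' @examples
#' injection_distance("ALM", "MOs")  # ~1.105
injection_distance <- function(region_a, region_b,
                               catalog = region_catalog(), dims = 3) {
  region_a <- canonical_region(region_a); region_b <- canonical_region(region_b)
  ia <- match(region_a, catalog$region); ib <- match(region_b, catalog$region)
  if (anyNA(ia)) stop("unknown region: ", region_a[which(is.na(ia))[1]])
  if (anyNA(ib)) stop("unknown region: ", region_b[which(is.na(ib))[1]])
  cols <- if (dims == 3) c("ap_mm", "ml_mm", "dv_mm") else c("ap_mm", "ml_mm")
  a <- as.matrix(catalog[ia, cols]); b <- as.matrix(catalog[ib, cols])
  unname(sqrt(rowSums((a - b)^2)))
}

#' Unique pathway pairs across a set of experiments
#'
#' Enumerates the unordered region pairs simultaneously labeled within
#' each experiment (off-target channels excluded) and returns the unique
#' pairs across all experiments.
#'
#' @param experiments list of [tracing_experiment()]s (default: the
#'   packaged experiment designs, which yield 27 pairs).
#' @return data.frame `region_a`, `region_b` (sorted within pair).
#' @export
design_pairs <- function(experiments = packaged_experiments()) {
  pairs <- list()
  for (exp in experiments) {
    regs <- sort(channel_region(exp, analyzed_channels(exp)))
    if (length(regs) < 2) next
    for (p in combn(regs, 2, simplify = FALSE))
      pairs[[paste(p, collapse = "|")]] <- p
  }
  pairs <- pairs[sort(names(pairs))]
  data.frame(region_a = vapply(pairs, `[`, "", 1),
             region_b = vapply(pairs, `[`, "", 2), row.names = NULL)
}

#' Reduce pathway pairs for the connectivity comparison
#'
#' The external connectivity table does not separate rostrocaudal levels
#' of the retrosplenial cortex and has no entry at the ALM coordinate, so
#' rRSP/iRSP/cRSP are relabeled RSP, pairs containing ALM are removed,
#' and same-region pairs collapse away. The packaged 27-pair design
#' reduces to 19 pairs.
#'
#' @param pairs data.frame with `region_a`, `region_b`.
#' @return reduced unique pair data.frame.
#' @export
reduce_pairs_for_connectivity <- function(pairs) {
  relabel <- function(r) ifelse(r %in% c("rRSP", "iRSP", "cRSP"), "RSP", r)
  a <- relabel(canonical_region(pairs$region_a))
  b <- relabel(canonical_region(pairs$region_b))
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- lo != hi & lo != "ALM" & hi != "ALM"
  key <- unique(paste(lo[keep], hi[keep], sep = "|"))
  key <- sort(key)
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(region_a = vapply(parts, `[`, "", 1),
             region_b = vapply(parts, `[`, "", 2), row.names = NULL)
}

#' Pearson correlation on per-pair grand means
#'
#' Replicate values (e.g. per mouse) are averaged within each pathway pair
#' first; the correlation coefficient is computed on the grand means.
#'
#' @param pair pair identifier per observation.
#' @param x,y numeric observations.
#' @return list with `r`, `n_pairs`, and the per-pair means.
#' @export
correlate_grand_means <- function(pair, x, y) {
  mx <- tapply(x, pair, mean); my <- tapply(y, pair, mean)
  if (length(mx) < 3) stop("need >= 3 pairs to correlate")
  if (sd(mx) == 0 || sd(my) == 0)
    stop("zero variance: correlation undefined")
  list(r = cor(as.numeric(mx), as.numeric(my)), n_pairs = length(mx),
       means = data.frame(pair = names(mx), x = as.numeric(mx),
                          y = as.numeric(my), row.names = NULL))
}

#' Pairwise two-group tests with Bonferroni correction
#'
#' Pairwise t tests (or Wilcoxon rank-sum / signed-rank tests) between all
#' groups, with the Bonferroni family defined as the set of comparisons
#' performed here: adjusted p = min(1, m * p). Comparisons with fewer than
#' two observations in a group are skipped with a warning.
#'
#' @param values numeric observations.
#' @param group group label per observation.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @param paired paired comparisons (observations matched by order within
#'   group).
#' @return data.frame with `group_a`, `group_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `significant` (adjusted p < .05).
#' @export
pairwise_tests <- function(values, group, method = c("t", "wilcoxon"),
                           paired = FALSE) {
  method <- match.arg(method)
  groups <- sort(unique(as.character(group)))
  comps <- combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (cp in comps) {
    a <- values[group == cp[1]]; b <- values[group == cp[2]]
    if (length(a) < 2 || length(b) < 2 || (paired && length(a) != length(b))) {
      warning("skipping ", cp[1], " vs ", cp[2], ": insufficient observations")
      next
    }
    if (method == "t") {
      if (sd(c(a, b)) == 0) {
        tt <- list(statistic = 0, p.value = 1)  # identical groups
      } else tt <- t.test(a, b, paired = paired)
    } else {
      tt <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = cp[1], group_b = cp[2],
      statistic = unname(tt$statistic), p_raw = tt$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  m <- nrow(out)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$significant <- out$p_adjusted < 0.05
  out
}

#' Two-sample t test from printed summary statistics
#'
#' Recomputes a two-sample t statistic from group means, SDs and sizes,
#' as needed to check statistics reported only as `mean +/- SD`.
#' With `var_equal = FALSE` (default) the Welch statistic is returned;
#' for equal group sizes the pooled and Welch statistics coincide.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @param var_equal pool the variances.
#' @return list with `t`, `df`, `p`.
#' @export
#' @examples
#' t_from_summary(8.3, 3.3, 34, 4.1, 3.1, 34)$t  # ~5.41
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           var_equal = FALSE) {
  if (var_equal) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Assemble a pathway-pair association table
#'
#' Joins per-mouse co-projection rates with module spatial overlap,
#' injection-site distance, and (optionally) symmetrized corticocortical
#' connectivity, one row per (pair, mouse) replicate.
#'
#' @param rates data.frame with `region_a`, `region_b`, `mouse_id`,
#'   `coprojection_rate`.
#' @param overlaps optional data.frame with `region_a`, `region_b`,
#'   `spatial_overlap` (per pair).
#' @param connectivity optional symmetrized table
#'   ([symmetrize_connectivity()]); region pairs are reduced with
#'   [reduce_pairs_for_connectivity()] semantics for the lookup.
#' @param catalog region catalog for distances.
#' @return data.frame with added `injection_distance_mm`,
#'   `spatial_overlap`, `connectivity` columns (NA where unavailable).
#' @export
pair_associations <- function(rates, overlaps = NULL, connectivity = NULL,
                              catalog = region_catalog()) {
  out <- rates
  out$region_a <- canonical_region(out$region_a)
  out$region_b <- canonical_region(out$region_b)
  out$injection_distance_mm <-
    injection_distance(out$region_a, out$region_b, catalog)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  if (!is.null(overlaps)) {
    idx <- match(key(out$region_a, out$region_b),
                 key(canonical_region(overlaps$region_a),
                     canonical_region(overlaps$region_b)))
    out$spatial_overlap <- overlaps$spatial_overlap[idx]
  }
  if (!is.null(connectivity)) {
    relabel <- function(r) ifelse(r %in% c("rRSP", "iRSP", "cRSP"), "RSP", r)
    a <- relabel(out$region_a); b <- relabel(out$region_b)
    conn <- rep(NA_real_, nrow(out))
    usable <- a != b & a != "ALM" & b != "ALM"
    conn[usable] <- connectivity_strength(connectivity, a[usable], b[usable])
    out$connectivity <- conn
  }
  out
}
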