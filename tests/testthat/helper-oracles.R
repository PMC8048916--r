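# Independent brute-force oracles used to check the implementation.

# ray-casting point-in-polygon (boundary points counted inside via eps test)
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      if ((vy[k] > y) != (vy[j] > y)) {
        xint <- vx[k] + (y - vy[k]) / (vy[j] - vy[k]) * (vx[j] - vx[k])
        if (x < xint) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

# gift-wrapping convex hull, returns vertex indices (ccw)
oracle_gift_wrap <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-12 * y)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cross <- (x[q] - x[p]) * (y[r] - y[p]) - (y[q] - y[p]) * (x[r] - x[p])
      d_q <- (x[q] - x[p])^2 + (y[q] - y[p])^2
      d_r <- (x[r] - x[p])^2 + (y[r] - y[p])^2
      if (cross < 0 || (cross == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrap failed")
  }
  hull
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# exhaustive Otsu: minimize within-class variance over all histogram splits
oracle_otsu <- function(values, n_levels = 256) {
  rng <- range(values)
  width <- diff(rng) / n_levels
  lev <- pmin(floor((values - rng[1]) / width), n_levels - 1)
  mids <- rng[1] + (lev + 0.5) * width
  best <- Inf; best_k <- 1
  for (k in seq_len(n_levels - 1)) {
    lo <- mids[lev < k]; hi <- mids[lev >= k]
    if (length(lo) == 0 || length(hi) == 0) next
    wcv <- 0
    if (length(lo) > 1) wcv <- wcv + length(lo) * mean((lo - mean(lo))^2)
    if (length(hi) > 1) wcv <- wcv + length(hi) * mean((hi - mean(hi))^2)
    if (wcv < best) { best <- wcv; best_k <- k }
  }
  rng[1] + best_k * width
}

# greedy one-to-one matching replayed naively from a pair list
oracle_greedy_match <- function(ids_i, ids_j, dist) {
  ord <- order(dist, ids_i, ids_j)
  used_i <- character(); used_j <- character(); keep <- integer()
  for (k in ord) {
    if (ids_i[k] %in% used_i || ids_j[k] %in% used_j) next
    used_i <- c(used_i, ids_i[k]); used_j <- c(used_j, ids_j[k])
    keep <- c(keep, k)
  }
  keep
}

# random multiset of label sets over channels, with its uncorrected counts
random_label_instance <- function(channels, n, prob_multi = 0.4) {
  sets <- replicate(n, {
    k <- if (runif(1) < prob_multi)
      sample(seq_along(channels), 1) else 1
    label_string(sample(channels, k))
  })
  sets
}
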