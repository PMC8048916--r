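test_that("co-label matching respects the 50 um radius and one-to-one rule", {
  near <- make_cells(c(0, 6, 100, 160), c(0, 8, 0, 0),
                     c("A", "B", "A", "B"))
  m <- match_colabels(near)
  expect_equal(nrow(m), 1)  # 10 um pair matched, 60 um pair not
  expect_equal(m$distance_um, 10)

  # two A cells compete for one B cell: nearer pair wins
  comp <- make_cells(c(0, 30, 10), c(0, 0, 0), c("A", "A", "B"),
                     cell_id = c("a1", "a2", "b1"))
  m2 <- match_colabels(comp)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$cell_i, "a1")
})

test_that("greedy matching equals the replayed greedy oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:8, 2, replace = TRUE)
    det <- make_cells(runif(sum(n), 0, 120), runif(sum(n), 0, 120),
                      rep(c("A", "B"), n))
    m <- match_colabels(det, radius_um = 50)
    ai <- which(rep(c("A", "B"), n) == "A")
    bi <- which(rep(c("A", "B"), n) == "B")
    d <- sqrt(outer(det$x_um[ai], det$x_um[bi], "-")^2 +
              outer(det$y_um[ai], det$y_um[bi], "-")^2)
    cand <- which(d <= 50, arr.ind = TRUE)
    keep <- oracle_greedy_match(det$cell_id[ai[cand[, 1]]],
                                det$cell_id[bi[cand[, 2]]], d[cand])
    expect_equal(nrow(m), length(keep))
    expect_setequal(paste(m$cell_i, m$cell_j),
                    paste(det$cell_id[ai[cand[keep, 1]]],
                          det$cell_id[bi[cand[keep, 2]]]))
  }
})

test_that("label-set assembly is transitive and channel-consistent", {
  # chain A-B, B-C resolves to one {A,B,C} neuron
  det <- make_cells(c(0, 10, 20), c(0, 0, 0), c("A", "B", "C"))
  res <- resolve_colabels(det)
  expect_equal(nrow(res), 1)
  expect_equal(res$labels, "A;B;C")

  # no component may hold two same-channel detections
  det2 <- make_cells(c(0, 10, 20), c(0, 0, 0), c("A", "B", "A"),
                     cell_id = c("a1", "b1", "a2"))
  res2 <- resolve_colabels(det2)
  expect_equal(nrow(res2), 2)
  expect_setequal(res2$labels, c("A;B", "A"))
})

test_that("resolution recovers ground-truth label sets with perfect tracers", {
  # well-separated modules: co-detections of one neuron sit at distance 0,
  # unrelated cross-channel detections are hundreds of um apart
  pw <- list(R = pathway_model("iRSP", 0, -300, 60, 60, c(30, 30, 30)),
             M = pathway_model("MOs", 0, 300, 60, 60, c(30, 30, 30)))
  probs <- setNames(c(0.35, 0.35, 0.3),
                    c("iRSP", "MOs", label_string(c("iRSP", "MOs"))))
  cp <- coprojection_model(probs, c(iRSP = 1, MOs = 1))
  sim <- generate_experiment(pw, cp, seed = 17, detection_jitter_um = 0,
                             reference = "iRSP")
  res <- resolve_colabels(sim$detections)
  expect_equal(sort(res$labels), sort(sim$truth$true_set))
})

test_that("pattern combinatorics give 2^k - 1", {
  expect_equal(enumerate_patterns(4), 15)
  expect_equal(enumerate_patterns(1), 1)
  expect_equal(enumerate_patterns(3), 7)
  expect_error(enumerate_patterns(0), "k must be")
  expect_equal(length(all_patterns(c("A", "B", "C", "D"))), 15)
})

test_that("uncorrected and exact counts obey the subset-sum identity", {
  set.seed(51)
  chans <- c("A", "B", "C")
  labs <- random_label_instance(chans, 200)
  u <- uncorrected_counts(labs, chans)
  e <- exact_counts(labs, chans)
  for (S in names(u)) {
    Ss <- strsplit(S, ";")[[1]]
    supersets <- names(e)[vapply(strsplit(names(e), ";"),
                                 function(T) all(Ss %in% T), TRUE)]
    expect_equal(u[[S]], sum(e[supersets]))
  }
  expect_equal(sum(e), length(labs))
})

test_that("inclusion-exclusion inverts uncorrected counts (1,000 instances)", {
  set.seed(52)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    chans <- LETTERS[1:k]
    labs <- random_label_instance(chans, sample(5:40, 1))
    u <- uncorrected_counts(labs, chans)
    ie <- inclusion_exclusion(u)
    expect_identical(unname(round(ie$exact)),
                     unname(as.numeric(exact_counts(labs, chans))))
    expect_equal(ie$union_count, length(labs))
  }
})

test_that("the packaged midline mouse M58 resolves to 1241 distinct neurons", {
  u <- packaged_uncorrected("M58")
  expect_equal(length(u), 15)
  expect_equal(u[["A"]], 676)
  expect_equal(u[["A;B;C;D"]], 38)
  ie <- suppressWarnings(inclusion_exclusion(u))
  expect_equal(ie$union_count, 1241)
  sizes <- lengths(strsplit(names(ie$exact), ";"))
  expect_equal(sum(ie$exact[sizes >= 3]), 137)
  # this real count table is slightly inconsistent (A;D inverts negative)
  expect_warning(inclusion_exclusion(u), "A;D")
  expect_error(inclusion_exclusion(u, strict = TRUE), "A;D")
})

test_that("all-singleton uncorrected counts invert to themselves", {
  u <- c(A = 5, B = 3, `A;B` = 0)
  ie <- inclusion_exclusion(u)
  expect_equal(ie$exact[["A"]], 5)
  expect_equal(ie$exact[["B"]], 3)
  expect_equal(ie$union_count, 8)
})

test_that("pooled midline mice have ~10% of neurons with >= 3 labels", {
  pooled <- packaged_uncorrected("M58") + packaged_uncorrected("M59")
  ie <- suppressWarnings(inclusion_exclusion(pooled))
  frac <- multi_target_fraction(ie$exact, 3)
  expect_equal(frac, 0.105, tolerance = 0.005)
  expect_equal(multi_target_fraction(ie$exact, 1), 1)
  singles <- c(A = 4, B = 6)
  expect_equal(multi_target_fraction(c(singles, `A;B` = 0), 2), 0)
})

test_that("co-projection rate matches the printed-count example", {
  expect_equal(jaccard_rate(482, 434, 131), 131 / (482 + 434 - 131))
  expect_equal(jaccard_rate(7, 7, 7), 1)
  expect_equal(jaccard_rate(4, 9, 0), 0)
  expect_error(jaccard_rate(3, 3, 4), "exceeds")
  expect_error(jaccard_rate(0, 0, 0), "undefined")
  # symmetry and range on random counts
  set.seed(53)
  for (i in 1:50) {
    ab <- sample(0:20, 1)
    a <- ab + sample(0:30, 1); b <- ab + sample(0:30, 1)
    if (a + b == 0) next
    j <- jaccard_rate(a, b, ab)
    expect_equal(j, jaccard_rate(b, a, ab))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("pairwise Jaccard matrix is symmetric with unit diagonal", {
  u <- packaged_uncorrected("M176")
  m <- pairwise_jaccard(u)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["A", "B"], 131 / (482 + 434 - 131))
})

test_that("capture-recapture recovers detection probabilities", {
  d <- detection_probability(0, 0, 50)
  expect_equal(d$p_a, 1); expect_equal(d$max_observable_jaccard, 1)
  d2 <- detection_probability(30, 30, 70)
  expect_equal(d2$p_a, 0.7)
  expect_equal(d2$max_observable_jaccard, 0.49 / 0.91)
  expect_error(detection_probability(5, 5, 0), "inestimable")

  # simulation recovery: true p_a = 0.6, p_b = 0.8 over 10,000 neurons
  set.seed(54)
  n <- 10000
  a <- runif(n) < 0.6; b <- runif(n) < 0.8
  est <- detection_probability(sum(a & !b), sum(!a & b), sum(a & b))
  expect_equal(est$p_a, 0.6, tolerance = 0.02 / 0.6)
  expect_equal(est$p_b, 0.8, tolerance = 0.02 / 0.8)
})

test_that("observed co-projection falls as detection degrades", {
  set.seed(55)
  n <- 20000
  true_ab <- 0.3  # fraction of latent neurons projecting to both
  lab <- sample(c("A", "B", "A;B"), n, replace = TRUE,
                prob = c(0.35, 0.35, true_ab))
  rates <- vapply(c(1, 0.85, 0.7, 0.55), function(p) {
    hasA <- grepl("A", lab) & runif(n) < p
    hasB <- grepl("B", lab) & runif(n) < p
    jaccard_rate(sum(hasA), sum(hasB), sum(hasA & hasB))
  }, 0)
  expect_true(all(diff(rates) < 0))
  # matches the closed-form attenuation within Monte-Carlo error
  r_true <- true_ab / (0.35 + 0.35 + true_ab)
  expect_equal(rates[3], expected_observed_jaccard(0.7, 0.7, r_true),
               tolerance = 0.05)
})
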