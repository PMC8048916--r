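test_that("expected observed co-projection rate has the right limits", {
  for (r in c(0, 0.3, 1))
    expect_equal(expected_observed_jaccard(1, 1, r), r)
  expect_equal(expected_observed_jaccard(0.4, 0.8, 0), 0)
  expect_equal(expected_observed_jaccard(0.7, 0.7, 1), 0.49 / 0.91)
  expect_error(expected_observed_jaccard(0, 0.5, 1), "detection")
  expect_error(expected_observed_jaccard(0.5, 0.5, 1.2), "true_rate")
})

test_that("singleton target sets produce zero observed co-labeling", {
  pw <- default_pathways(c("iRSP", "MOs", "ALM"))
  cp <- default_coprojection(pw, detection_prob = c(iRSP = 1, MOs = 1,
                                                    ALM = 1))
  sim <- generate_experiment(pw, cp, seed = 3)
  u <- uncorrected_counts(sim$cells, channels = c("iRSP", "MOs", "ALM"))
  multi <- u[grepl(";", names(u))]
  expect_true(all(multi == 0))
})

test_that("perfect detection reproduces the latent target-set multiset", {
  pw <- default_pathways(c("iRSP", "MOs"))
  cp <- default_coprojection(pw, detection_prob = c(iRSP = 1, MOs = 1),
                             coproj_sets = c(`MOs;iRSP` = 0.1))
  sim <- generate_experiment(pw, cp, seed = 5)
  expect_equal(nrow(sim$cells), nrow(sim$truth))
  expect_equal(sort(sim$cells$labels), sort(sim$truth$true_set))
})

test_that("observed labels are always a subset of the true target set", {
  pw <- default_pathways(c("iRSP", "PL"))
  cp <- default_coprojection(pw, detection_prob = c(iRSP = 0.6, PL = 0.8),
                             coproj_sets = c(`PL;iRSP` = 0.15))
  sim <- generate_experiment(pw, cp, seed = 8)
  tr <- sim$truth[!is.na(sim$truth$observed_labels), ]
  ok <- mapply(function(obs, true)
    all(strsplit(obs, ";")[[1]] %in% strsplit(true, ";")[[1]]),
    tr$observed_labels, tr$true_set)
  expect_true(all(ok))
})

test_that("a fully co-projecting population attenuates to p/(2-p)", {
  # one latent population projecting to both regions
  pw <- list(A = pathway_model("iRSP", 0, 0, 100, 100),
             B = pathway_model("PL", 0, 0, 100, 100))
  cp <- coprojection_model(c(`PL;iRSP` = 1),
                           c(iRSP = 0.7, PL = 0.7))
  sim <- generate_experiment(pw, cp, seed = 9, n_latent_per_slice = 1700,
                             reference = "iRSP")
  u <- uncorrected_counts(sim$cells, channels = c("iRSP", "PL"))
  j <- jaccard_rate(u[["PL"]], u[["iRSP"]], u[["PL;iRSP"]])
  expect_equal(j, expected_observed_jaccard(0.7, 0.7, 1), tolerance = 0.04)

  cp1 <- coprojection_model(c(`PL;iRSP` = 1), c(iRSP = 1, PL = 1))
  sim1 <- generate_experiment(pw, cp1, seed = 9, n_latent_per_slice = 300,
                              reference = "iRSP")
  u1 <- uncorrected_counts(sim1$cells, channels = c("iRSP", "PL"))
  expect_equal(jaccard_rate(u1[["PL"]], u1[["iRSP"]], u1[["PL;iRSP"]]), 1)
})

test_that("observed per-region counts match marginal x detection", {
  pw <- list(R = pathway_model("iRSP", 0, 0, 100, 100),
             M = pathway_model("MOs", 150, 0, 120, 120))
  probs <- c(0.5, 0.3, 0.2)
  names(probs) <- c("iRSP", "MOs", label_string(c("iRSP", "MOs")))
  cp <- coprojection_model(probs, c(iRSP = 0.8, MOs = 0.6))
  n <- 10000
  sim <- generate_experiment(pw, cp, seed = 2, n_slices_per_rc = 1,
                             n_latent_per_slice = c(rostral = n,
                                                    intermediate = 0,
                                                    caudal = 0),
                             reference = "iRSP")
  n_latent <- nrow(sim$truth)
  u <- uncorrected_counts(sim$cells, channels = c("iRSP", "MOs"))
  exp_rsp <- n_latent * (0.5 + 0.2) * 0.8
  exp_mos <- n_latent * (0.3 + 0.2) * 0.6
  expect_lt(abs(u[["iRSP"]] - exp_rsp), 4 * sqrt(exp_rsp))
  expect_lt(abs(u[["MOs"]] - exp_mos), 4 * sqrt(exp_mos))
})

test_that("zone calibration matches packaged zone fractions", {
  z <- zone_fraction_table()
  for (r in c("ALM", "ACA", "ENTl", "MOs", "cRSP")) {
    zr <- z[z$region == r & z$rc_level == "rostral", ]
    cal <- calibrate_pathway(zr$dorsal_pct, zr$core_pct)
    expect_equal(100 * cal$achieved[["dorsal_shell"]], zr$dorsal_pct,
                 tolerance = 0.02)
    expect_equal(100 * cal$achieved[["core"]], zr$core_pct,
                 tolerance = 0.02)
  }
})

test_that("zone probabilities integrate to one and respect symmetry", {
  z <- zone_probabilities(0, 100)
  expect_equal(sum(z), 1)
  expect_equal(z[["dorsal_shell"]], z[["ventral_shell"]], tolerance = 1e-6)
  expect_equal(z[["core"]], 0.9, tolerance = 1e-6)
  zd <- zone_probabilities(200, 150)
  expect_gt(zd[["dorsal_shell"]], zd[["ventral_shell"]])
})

test_that("pipeline recovers a 70% dorsal-shell module within 3 points", {
  pw <- recovery_pathways()
  cp <- default_coprojection(pw, detection_prob = c(iRSP = 1, ALM = 1))
  sim <- generate_experiment(pw, cp, seed = 42)
  cl <- classify_cells(sim$cells, "iRSP")
  alm <- cl$cells[has_channel(cl$cells, "ALM") &
                  cl$cells$hemisphere == "ipsi", ]
  expect_gte(nrow(alm), 2000)
  expect_equal(100 * mean(alm$zone == "dorsal_shell"), 70, tolerance = 3 / 70)
})

test_that("per-mouse seed substreams are independent of study size", {
  pw <- default_pathways(c("iRSP", "MOs"))
  cp <- default_coprojection(pw)
  d <- list(pathways = pw, coproj = cp)
  s2 <- generate_study(list(a = d, b = d), seed = 10)
  s3 <- generate_study(list(a = d, b = d, c = d), seed = 10)
  a2 <- s2$cells[s2$cells$mouse_id == "a", ]
  a3 <- s3$cells[s3$cells$mouse_id == "a", ]
  expect_equal(a2, a3)
})

test_that("generator configuration errors are reported", {
  pw <- default_pathways(c("iRSP", "MOs"))
  cp <- default_coprojection(pw)
  expect_error(generate_experiment(pw["MOs"], cp, reference = "iRSP"),
               "reference")
  expect_error(coprojection_model(numeric(0), c(A = 1)), "empty")
  expect_error(coprojection_model(c(A = 0.5), c(A = 1)), "sum to 1")
  expect_error(coprojection_model(c(A = 1), c(A = 1.2)), "detection")
})
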