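# Generative model of multicolor retrograde tracing experiments.
#
# Latent claustrum neurons are drawn per slice; each neuron carries a true
# target set (the cortical regions it projects to) drawn from a
# distribution over region subsets, a position drawn from the equal-weight
# mixture of its targets' 2D Gaussian modules, and is observed in each
# targeted channel independently with that tracer's detection probability
# (< 1: tracers under-report projections). Neurons observed in no channel
# are dropped; ground truth is retained for every latent neuron.

#' Spatial/count model of one claustrocortical pathway
#'
#' A pathway's module is a 2D Gaussian in the reference-centered frame
#' (x mediolateral, y dorsoventral, μm), displaced `dv_offset_um` dorsally
#' (negative = ventrally) from the reference centroid, with expected
#' per-slice neuron counts at each rostrocaudal level.
#'
#' @param region region name (canonicalized).
#' @param dv_offset_um,ml_offset_um module displacement from the reference
#'   centroid (μm).
#' @param dv_sd_um,ml_sd_um Gaussian spreads (μm, > 0).
#' @param count_by_rc length-3 numeric, expected neurons per slice at
#'   rostral / intermediate / caudal levels (non-negative; the packaged
#'   defaults decrease rostral to caudal).
#' @return object of class `pathway_model`.
#' @export
pathway_model <- function(region, dv_offset_um = 0, ml_offset_um = 0,
                          dv_sd_um = 100, ml_sd_um = dv_sd_um,
                          count_by_rc = c(rostral = 50, intermediate = 35,
                                          caudal = 20)) {
  if (dv_sd_um <= 0 || ml_sd_um <= 0) stop("spreads must be > 0")
  count_by_rc <- setNames(as.numeric(count_by_rc), RC_LEVELS)
  if (any(count_by_rc < 0) || any(!is.finite(count_by_rc)))
    stop("counts must be finite and >= 0")
  structure(list(region = canonical_region(region),
                 dv_offset_um = dv_offset_um, ml_offset_um = ml_offset_um,
                 dv_sd_um = dv_sd_um, ml_sd_um = ml_sd_um,
                 count_by_rc = count_by_rc),
            class = "pathway_model")
}

#' Co-projection / detection model
#'
#' @param target_set_probs named numeric vector: probability of each latent
#'   target set, names as sorted semicolon-joined region sets (see
#'   [label_string()]); must sum to 1.
#' @param detection_prob named numeric vector: per-channel (region)
#'   detection probability in (0, 1].
#' @return object of class `coprojection_model`.
#' @export
coprojection_model <- function(target_set_probs, detection_prob) {
  if (length(target_set_probs) == 0) stop("empty target_set_probs")
  if (abs(sum(target_set_probs) - 1) > 1e-8)
    stop("target_set_probs must sum to 1")
  if (any(target_set_probs < 0)) stop("negative target-set probability")
  if (any(detection_prob <= 0 | detection_prob > 1))
    stop("detection probabilities must lie in (0, 1]")
  regions <- unique(unlist(strsplit(names(target_set_probs), ";")))
  missing_p <- setdiff(regions, names(detection_prob))
  if (length(missing_p) > 0)
    stop("no detection probability for: ", paste(missing_p, collapse = ", "))
  structure(list(target_set_probs = target_set_probs,
                 detection_prob = detection_prob),
            class = "coprojection_model")
}

#' Default per-tracer detection probabilities
#'
#' Tracers under-report projections; co-injection experiments bound the
#' observable co-labeling near 50-60%, consistent with per-tracer
#' detection probabilities around 0.6-0.75.
#'
#' @return named numeric vector per tracer.
#' @export
default_detection_probs <- function() {
  c(FB = 0.75, CTB647 = 0.70, `rAAV2-GFP` = 0.65, `rAAV2-tdTomato` = 0.65)
}

## ---- zone-fraction calibration --------------------------------------------

#' Core radius of the reference module
#'
#' Radius containing a given fraction of an isotropic 2D Gaussian: the
#' closest-`keep_fraction` polygon of a large reference sample approaches
#' the disc of this radius.
#'
#' @param ref_sd_um reference module spread (μm).
#' @param keep_fraction core fraction (default 0.9).
#' @return radius in μm.
#' @export
reference_core_radius <- function(ref_sd_um, keep_fraction = 0.9) {
  ref_sd_um * sqrt(qchisq(keep_fraction, df = 2))
}

#' Model zone probabilities of a displaced isotropic Gaussian module
#'
#' Probability that a neuron from an isotropic Gaussian module displaced
#' `dv_offset_um` dorsoventrally falls in the core (inside the reference
#' disc of [reference_core_radius()]), the dorsal shell (outside, y >= 0)
#' or the ventral shell (outside, y < 0).
#'
#' @param dv_offset_um module displacement (μm).
#' @param sd_um module spread (μm).
#' @param ref_sd_um reference module spread (μm).
#' @param keep_fraction core fraction (default 0.9).
#' @return named numeric: `core`, `dorsal_shell`, `ventral_shell` (sums to 1).
#' @export
zone_probabilities <- function(dv_offset_um, sd_um, ref_sd_um = 100,
                               keep_fraction = 0.9) {
  R <- reference_core_radius(ref_sd_um, keep_fraction)
  core <- pchisq((R / sd_um)^2, df = 2, ncp = (dv_offset_um / sd_um)^2)
  inside_dorsal <- integrate(function(y)
    dnorm(y, dv_offset_um, sd_um) *
      (2 * pnorm(sqrt(pmax(R^2 - y^2, 0)) / sd_um) - 1),
    0, R, rel.tol = 1e-9)$value
  dorsal <- pnorm(dv_offset_um / sd_um) - inside_dorsal
  c(core = core, dorsal_shell = dorsal,
    ventral_shell = 1 - core - dorsal)
}

#' Calibrate a module's offset and spread to target zone fractions
#'
#' Finds the dorsoventral offset and isotropic spread whose model zone
#' probabilities ([zone_probabilities()]) match target dorsal-shell and
#' core percentages (the ventral fraction follows). Deterministic
#' least-squares fit; some extreme targets are matched only approximately.
#'
#' @param dorsal_pct,core_pct target percentages (0-100).
#' @param ref_sd_um,keep_fraction reference-module geometry.
#' @return list with `dv_offset_um`, `sd_um`, `achieved` (named fractions).
#' @export
calibrate_pathway <- function(dorsal_pct, core_pct, ref_sd_um = 100,
                              keep_fraction = 0.9) {
  pd <- dorsal_pct / 100; pc <- core_pct / 100
  pv <- 1 - pd - pc
  obj <- function(par) {
    z <- zone_probabilities(par[1], exp(par[2]), ref_sd_um, keep_fraction)
    (z["core"] - pc)^2 + (z["dorsal_shell"] - pd)^2
  }
  init <- c(sign(pd - pv) * ref_sd_um, log(ref_sd_um))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(dv_offset_um = fit$par[1], sd_um = exp(fit$par[2]),
       achieved = zone_probabilities(fit$par[1], exp(fit$par[2]),
                                     ref_sd_um, keep_fraction))
}

#' Default pathway models for the 14 packaged regions
#'
#' The reference pathway (iRSP) is an isotropic Gaussian of spread
#' `ref_sd_um` at the origin; every other module's offset and spread are
#' calibrated ([calibrate_pathway()]) to the packaged rostral zone
#' fractions, and per-slice expected counts are taken from the packaged
#' count table at each rostrocaudal level.
#'
#' @param regions regions to include (default: all 14).
#' @param ref_sd_um reference module spread (default 100 μm).
#' @param keep_fraction core fraction (default 0.9).
#' @return named list of [pathway_model()]s.
#' @export
default_pathways <- function(regions = NULL, ref_sd_um = 100,
                             keep_fraction = 0.9) {
  z <- zone_fraction_table()
  if (is.null(regions)) regions <- unique(z$region)
  regions <- canonical_region(regions)
  out <- list()
  for (r in regions) {
    zr <- z[z$region == r, ]
    zr <- zr[match(RC_LEVELS, as.character(zr$rc_level)), ]
    counts <- setNames(zr$count_mean, RC_LEVELS)
    if (r == "iRSP") {
      out[[r]] <- pathway_model(r, 0, 0, ref_sd_um, ref_sd_um, counts)
    } else {
      rostral <- zr[zr$rc_level == "rostral", ]
      cal <- calibrate_pathway(rostral$dorsal_pct, rostral$core_pct,
                               ref_sd_um, keep_fraction)
      out[[r]] <- pathway_model(r, cal$dv_offset_um, 0, cal$sd_um,
                                cal$sd_um, counts)
    }
  }
  out
}

#' Default co-projection model for a set of pathways
#'
#' Marginal target probabilities are proportional to each pathway's mean
#' expected count; named multi-target sets take probability mass
#' `coproj_sets`, and singleton probabilities absorb the remainder so that
#' marginals are preserved.
#'
#' @param pathways named list of [pathway_model()]s.
#' @param detection_prob named per-region detection probabilities; default
#'   maps each region's first packaged tracer through
#'   [default_detection_probs()] (0.7 for regions outside the catalog).
#' @param coproj_sets named numeric vector of multi-target set
#'   probabilities (names as in [label_string()]); default none.
#' @return [coprojection_model()].
#' @export
default_coprojection <- function(pathways, detection_prob = NULL,
                                 coproj_sets = NULL) {
  regions <- vapply(pathways, `[[`, "", "region")
  w <- vapply(pathways, function(p) mean(p$count_by_rc), 0)
  names(w) <- regions
  w <- w / sum(w)
  if (is.null(detection_prob)) {
    cat14 <- region_catalog()
    tracer1 <- vapply(strsplit(cat14$tracers, ";"), `[`, "", 1)
    names(tracer1) <- cat14$region
    dp <- default_detection_probs()
    detection_prob <- vapply(regions, function(r)
      if (r %in% names(tracer1)) dp[[tracer1[[r]]]] else 0.7, 0)
    names(detection_prob) <- regions
  }
  probs <- setNames(w, regions)
  if (!is.null(coproj_sets) && length(coproj_sets) > 0) {
    for (s in names(coproj_sets)) {
      members <- strsplit(s, ";")[[1]]
      if (!all(members %in% regions))
        stop("co-projection set references unknown region in '", s, "'")
      probs[members] <- probs[members] - coproj_sets[[s]]
    }
    if (any(probs < -1e-12))
      stop("co-projection set mass exceeds a region's marginal probability")
    probs[probs < 0] <- 0
    probs <- c(probs, coproj_sets)
  }
  probs <- probs / sum(probs)
  names(probs) <- vapply(strsplit(names(probs), ";"),
                         function(x) label_string(x), "")
  coprojection_model(probs, detection_prob)
}

## ---- generation ------------------------------------------------------------

#' Generate one synthetic multicolor tracing experiment
#'
#' Per slice, latent neurons are drawn Poisson around the slice intensity;
#' each receives a target set from the co-projection model, a position from
#' the equal-weight mixture of its targets' module Gaussians (plus a rigid
#' per-slice field-of-view offset, which registration must undo), and is
#' detected in each targeted channel independently with that channel's
#' detection probability. Undetected neurons are dropped from the observed
#' table but kept in the ground truth. True zones follow the disc model of
#' [zone_probabilities()].
#'
#' @param pathways named list of [pathway_model()]s; must include the
#'   reference pathway.
#' @param coproj [coprojection_model()].
#' @param n_slices_per_rc slices per rostrocaudal level (default 2).
#' @param seed integer seed (all randomness).
#' @param mouse_id identifier for the generated mouse.
#' @param reference region name of the reference pathway (default
#'   `"iRSP"`).
#' @param n_latent_per_slice optional override of the latent-neuron
#'   intensity per slice (scalar or named per rc_level); by default derived
#'   from the pathway count table and the expected number of observed
#'   label-instances per latent neuron.
#' @param contra_fraction probability a neuron is contralateral (default
#'   0); the contra/ipsi count ratio is then `f / (1 - f)` in expectation.
#' @param slice_jitter_um half-width of the uniform per-slice rigid offset
#'   (default 150 μm).
#' @param detection_jitter_um per-channel positional jitter of detections
#'   (default 0: all channels of a neuron share its position).
#' @param keep_fraction core fraction used for true zones (default 0.9).
#' @return list with `cells` (observed resolved neurons; `labels` =
#'   detected channel set), `detections` (one row per detected channel,
#'   single-channel labels; input format of [resolve_colabels()]),
#'   `truth` (every latent neuron: true set, true zone, true position,
#'   observed labels or `NA` if dropped) and `detection_prob`.
#' @export
generate_experiment <- function(pathways, coproj, n_slices_per_rc = 2,
                                seed = 1, mouse_id = "sim1",
                                reference = "iRSP",
                                n_latent_per_slice = NULL,
                                contra_fraction = 0,
                                slice_jitter_um = 150,
                                detection_jitter_um = 0,
                                keep_fraction = 0.9) {
  regions <- vapply(pathways, `[[`, "", "region")
  names(pathways) <- regions
  if (!reference %in% regions)
    stop("reference pathway '", reference, "' not among the pathway models")
  if (length(coproj$target_set_probs) == 0) stop("empty target_set_probs")
  set.seed(as.integer(seed %% .Machine$integer.max))

  sets <- strsplit(names(coproj$target_set_probs), ";")
  set_probs <- as.numeric(coproj$target_set_probs)
  pdet <- coproj$detection_prob
  ref_sd <- pathways[[reference]]$dv_sd_um
  R90 <- reference_core_radius(ref_sd, keep_fraction)

  # expected observed label-instances per latent neuron
  e_inst <- sum(set_probs * vapply(sets, function(s) sum(pdet[s]), 0))
  lambda <- vapply(RC_LEVELS, function(rc) {
    if (!is.null(n_latent_per_slice)) {
      if (length(n_latent_per_slice) == 1) return(as.numeric(n_latent_per_slice))
      return(as.numeric(n_latent_per_slice[[rc]]))
    }
    total <- sum(vapply(pathways, function(p) p$count_by_rc[[rc]], 0))
    total / e_inst
  }, 0)

  # per-region parameter lookups for vectorized position draws
  ml_off <- vapply(pathways, `[[`, 0, "ml_offset_um")
  dv_off <- vapply(pathways, `[[`, 0, "dv_offset_um")
  ml_sd <- vapply(pathways, `[[`, 0, "ml_sd_um")
  dv_sd <- vapply(pathways, `[[`, 0, "dv_sd_um")
  set_strings <- vapply(sets, label_string, "")

  cells <- list(); detections <- list(); truth <- list()
  neuron <- 0L
  for (rc in RC_LEVELS) for (sl in seq_len(n_slices_per_rc)) {
    slice_id <- sprintf("%s_%s_s%d", mouse_id, rc, sl)
    off <- runif(2, -slice_jitter_um, slice_jitter_um)
    n <- rpois(1, lambda[[rc]])
    if (n == 0) next
    set_idx <- sample.int(length(sets), n, replace = TRUE, prob = set_probs)
    hemi <- ifelse(runif(n) < contra_fraction, "contra", "ipsi")
    anchor <- vapply(sets[set_idx], function(S)
      if (length(S) == 1) S else sample(S, 1), "")
    x <- rnorm(n, ml_off[anchor], ml_sd[anchor])
    y <- rnorm(n, dv_off[anchor], dv_sd[anchor])
    zone <- ifelse(sqrt(x^2 + y^2) <= R90, "core",
                   ifelse(y >= 0, "dorsal_shell", "ventral_shell"))
    # independent per-channel detection over each neuron's target set
    obs <- matrix(FALSE, n, length(regions), dimnames = list(NULL, regions))
    for (r in regions) {
      member <- vapply(sets[set_idx], function(S) r %in% S, logical(1))
      obs[, r] <- member & runif(n) < pdet[[r]]
    }
    obs_labels <- apply(obs, 1, function(v)
      if (any(v)) label_string(regions[v]) else NA_character_)
    cid <- sprintf("%s_c%06d", mouse_id, neuron + seq_len(n))
    neuron <- neuron + n
    truth[[length(truth) + 1L]] <- data.frame(
      cell_id = cid, mouse_id = mouse_id, slice_id = slice_id,
      rc_level = rc, hemisphere = hemi, true_x_um = x, true_y_um = y,
      true_zone = zone, true_set = set_strings[set_idx],
      observed_labels = obs_labels, stringsAsFactors = FALSE)
    seen <- !is.na(obs_labels)
    if (!any(seen)) next
    cells[[length(cells) + 1L]] <- data.frame(
      cell_id = cid[seen], mouse_id = mouse_id, slice_id = slice_id,
      rc_level = rc, hemisphere = hemi[seen],
      x_um = x[seen] + off[1], y_um = y[seen] + off[2],
      labels = obs_labels[seen], stringsAsFactors = FALSE)
    for (r in regions) {
      hit <- which(obs[, r])
      if (length(hit) == 0) next
      jx <- if (detection_jitter_um > 0)
        rnorm(length(hit), 0, detection_jitter_um) else 0
      jy <- if (detection_jitter_um > 0)
        rnorm(length(hit), 0, detection_jitter_um) else 0
      detections[[length(detections) + 1L]] <- data.frame(
        cell_id = paste0(cid[hit], "_", r), mouse_id = mouse_id,
        slice_id = slice_id, rc_level = rc, hemisphere = hemi[hit],
        x_um = x[hit] + off[1] + jx, y_um = y[hit] + off[2] + jy,
        labels = r, stringsAsFactors = FALSE)
    }
  }
  if (length(cells) == 0) stop("generator produced no observed neurons")
  list(cells = do.call(rbind, cells),
       detections = do.call(rbind, detections),
       truth = do.call(rbind, truth),
       detection_prob = pdet, reference = reference,
       lambda_per_slice = lambda)
}

#' Generate a multi-mouse synthetic study
#'
#' Runs [generate_experiment()] once per mouse with a documented
#' per-mouse seed substream (`seed + 1000 * mouse index`), so adding a
#' mouse never perturbs the data of another.
#'
#' @param designs named list (one element per mouse) of argument lists for
#'   [generate_experiment()] (at minimum `pathways` and `coproj`).
#' @param seed base integer seed.
#' @return list with pooled `cells`, `detections`, `truth`.
#' @export
generate_study <- function(designs, seed = 1) {
  out <- lapply(seq_along(designs), function(i) {
    args <- designs[[i]]
    args$seed <- (seed + 1000 * i) %% .Machine$integer.max
    args$mouse_id <- names(designs)[i] %||% sprintf("sim%d", i)
    do.call(generate_experiment, args)
  })
  list(cells = do.call(rbind, lapply(out, `[[`, "cells")),
       detections = do.call(rbind, lapply(out, `[[`, "detections")),
       truth = do.call(rbind, lapply(out, `[[`, "truth")),
       experiments = out)
}

#' Expected observed co-projection rate under imperfect detection
#'
#' For two equal-size projection populations whose true co-projection
#' (Jaccard) rate is `true_rate`, with each tracer detecting its
#' projectors independently with probability `p_a` / `p_b`, the expected
#' observed rate (treating counts as expectations) is
#' `2 r p_a p_b / ((1 + r)(p_a + p_b) - 2 r p_a p_b)`. At `r = 1` this is
#' the detectability ceiling `p_a p_b / (p_a + p_b - p_a p_b)`; at
#' perfect detection it returns `r`.
#'
#' @param p_a,p_b detection probabilities in (0, 1].
#' @param true_rate true co-projection rate in \[0, 1\].
#' @return expected observed Jaccard rate.
#' @export
#' @examples
#' expected_observed_jaccard(0.7, 0.7, 1)  # ~0.538
expected_observed_jaccard <- function(p_a, p_b, true_rate) {
  if (p_a <= 0 || p_a > 1 || p_b <= 0 || p_b > 1)
    stop("detection probabilities must lie in (0, 1]")
  if (true_rate < 0 || true_rate > 1)
    stop("true_rate must lie in [0, 1]")
  num <- 2 * true_rate * p_a * p_b
  den <- (1 + true_rate) * (p_a + p_b) - 2 * true_rate * p_a * p_b
  num / den
}
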