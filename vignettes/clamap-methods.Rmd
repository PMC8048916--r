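---
title: "Mapping claustrocortical projection modules from multicolor retrograde tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping claustrocortical projection modules from multicolor retrograde tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamap)
```

## The problem

Retrograde tracers injected into a cortical region label the claustrum
neurons that project there. Injecting up to four distinguishable tracers
(fast blue, CTB-647, and two rAAV2-retro variants) into different cortical
regions of the same mouse yields, per coronal slice, a set of labeled
neuron coordinates per imaging channel. From such per-slice coordinate
tables, `clamap` answers three questions:

1. **Where** does each claustrocortical pathway sit within the claustrum
   (topography, core versus shell)?
2. **How much** do pathways share neurons (co-projection), and how is that
   bounded by tracer efficacy?
3. **What predicts** co-projection — spatial module overlap, distance
   between cortical targets, corticocortical connectivity?

The claustrum has no sharp cytoarchitectonic boundary in standard stains,
so all spatial statements are made relative to a *reference pathway*: the
neurons projecting to the retrosplenial cortex (RSP), which every
experiment labels at the same intermediate RSP coordinate.

## Registration and the core/shell frame

Each slice is processed independently. Coordinates are rotated, when
needed, so the dorsoventral axis is vertical; when no angle is supplied the
package can estimate one by making the first principal axis of the
reference population vertical (acquired images are usually already
aligned, so the default applies no rotation). All neurons are then
translated so that the centroid of the reference-channel neurons is the
origin. Registration is equivariant: translating the raw coordinates of a
slice leaves registered coordinates unchanged.

The **claustrum core** is the convex hull of the closest 90% of reference
neurons to their centroid; the most distant 10% are removed to suppress
spatial outliers. Because every retained point lies within the radius of
the furthest retained point, removed points fall strictly outside the
hull, and exactly `ceil(0.9 n)` of `n` reference neurons classify as core
on every slice — the reference pathway's core fraction is 90% by
construction. Neurons outside the hull are **dorsal shell** when their
registered dorsoventral coordinate is at or above the reference centroid
and **ventral shell** otherwise; the source method does not define the
split line, and the registered centroid height is the natural choice in
this frame. A minimum of three reference neurons per slice is required;
thinner slices are skipped with a warning. The hull is deterministic;
distance ties at the 90% cutoff break by cell id. A traced (concave)
perimeter would be an alternative reading of the original method; the
convex hull is used because it is parameter-free and makes the 90%
property exact.

## Density maps and module boundaries

Spatial density maps use 30 μm × 30 μm bins, half-open `[edge, edge+30)`,
with edges anchored at integer multiples of the bin size from the origin.
The extent is the bounding box of the registered neurons padded by one
bin; empty bins inside the extent participate in all statistics. Per
pathway, per-slice count maps are averaged within mouse, then across mice,
then peak-normalized before boundary extraction (the averaging order is
not dictated by the source method; mouse-first averaging weights animals
equally). The module outline is Otsu's threshold over the 256-level
histogram of bin values — the split maximizing between-class variance —
with the mask defined as `density >= threshold`. Spatial overlap between
two modules is `|A∩B| / (|A| + |B|)` in bins, bounded by 0.5 for identical
modules; this is kept exactly as the original overlap statistic rather
than converted to a Jaccard of areas.

## Co-labeling and labeling patterns

Manual multicolor counting records each channel separately; deciding that
a fast-blue neuron and a CTB neuron are the *same* cell uses a 50 μm
matching radius. The package automates this deterministically: within each
slice and unordered channel pair, cross-channel detection pairs within
50 μm are matched one-to-one greedily by ascending distance (ties by cell
id); matched pairs then merge by union-find into resolved neurons whose
label set is the union of member channels, discarding any edge that would
place two same-channel detections in one component.

With `k` tracers a neuron can adopt `2^k − 1` labeling patterns (15 for
four-color tracing). Counts are tabulated two ways:

* **uncorrected** — a neuron contributes to every non-empty subset of its
  label set (the convention of the packaged experiment table);
* **exact** — neurons whose label set equals the pattern, obtained from
  uncorrected counts by Möbius inversion:
  `exact(S) = Σ_{T ⊇ S} (−1)^{|T|−|S|} uncorrected(T)`.

The number of distinct neurons is the sum of exact counts. Manually
counted tables can be slightly inconsistent; one packaged midline mouse
inverts to a small negative exact count for one two-channel pattern
(A;D = −11 of 1241 neurons). Inversion therefore warns rather than fails
by default (`strict = TRUE` restores the hard error); the union and the
≥3-label counts are unaffected by where that small inconsistency lies.

The pairwise co-projection rate is `AB / (A + B − AB)` on uncorrected
counts — deliberately so, matching the original formula, even when
higher-order labels exist.

## Tracer efficacy and the detectability ceiling

Co-injecting two tracers at one site marks the same projection population
twice, a capture–recapture design. Lincoln–Petersen gives
`p_A = AB/(AB + B_only)` and `p_B = AB/(AB + A_only)`, and the maximum
observable co-projection rate between tracers A and B is
`p_A p_B / (p_A + p_B − p_A p_B)` — about 0.54 at `p = 0.7`, i.e. even a
fully co-projecting population appears only ~50–60% co-labeled. For a
population whose true co-projection rate is `r`, assuming two equal-size
projection populations and independent detection, the expected observed
rate is `2 r p_A p_B / ((1+r)(p_A + p_B) − 2 r p_A p_B)`; the equal-size
assumption is ours (the general case depends on both population sizes
separately) and reduces to the ceiling at `r = 1` and to `r` under perfect
detection.

## The synthetic-data generator

No public per-neuron coordinate data accompany the printed tables, so the
generator is a first-class, tested component that emulates the experiments'
structure with known ground truth:

* **Modules.** Each pathway is an isotropic 2D Gaussian in the
  reference-centered frame. The reference module has spread 100 μm at the
  origin (its 5/90/5 dorsal/core/ventral split is symmetric by
  construction); every other module's dorsoventral offset and spread are
  calibrated deterministically so that its model core probability (mass
  inside the reference 90% disc) and dorsal-shell probability match the
  packaged per-pathway zone percentages (rostral row). The calibration is
  numerical (noncentral-χ² core mass plus a 1-D integral for the dorsal
  split) and reproduces the targets to well under one percentage point.
* **Counts.** Expected per-slice neuron counts per pathway and
  rostrocaudal level come from the packaged count table (decreasing
  rostral → caudal); realized counts are Poisson. Two slices per level
  mirror the imaging design. A single level-independent target-set
  distribution cannot match every pathway's count profile exactly; marginal
  target probabilities are proportional to mean counts, and the latent
  intensity is scaled so total expected label-instances match the table.
* **Co-projection.** Each latent neuron draws a target set from a
  distribution over region subsets; its position comes from the
  equal-weight mixture of its targets' Gaussians (one target drawn
  uniformly), making co-projecting neurons spatially intermediate between
  modules, consistent with the observed overlap–co-projection coupling.
* **Detection.** Each targeted channel is observed independently with its
  tracer's detection probability (defaults 0.65–0.75 per tracer, the range
  implied by co-injection saturating near 50–60%). Neurons with no
  observed channel are dropped from the observed tables but retained in
  ground truth. Optional per-detection positional jitter exercises the
  50 μm matcher.
* **Context.** Each slice receives a rigid uniform field-of-view offset
  (±150 μm) that registration must undo; a configurable fraction of
  neurons is contralateral, so the contra/ipsi ratio recovers `f/(1−f)`.
* **Seeds.** One integer seed drives everything; multi-mouse studies give
  mouse `i` the substream `seed + 1000·i`, so adding a mouse never
  perturbs another's data.

What the generator does **not** emulate: anisotropic, curved claustrum
geometry; mediolateral module offsets; slice-to-slice biological
variability beyond Poisson counts; tracer competition at co-injected sites
(detection independence is assumed; the co-injection data show incomplete
overlap without identifying a mechanism); uncertainty in manual cell
identification. Passing tests on synthetic data therefore validate the
*pipeline arithmetic* under the stated generative assumptions, not the
biological conclusions drawn from real tissue.

## Statistical conventions

Association analyses average replicate (per-mouse) values within each
pathway pair first and correlate the grand means. Injection-site distance
is 3-D Euclidean over the stereotaxic (AP, ML, DV) coordinates by default
(whether the original used DV is unstated; 2-D is available). For the
corticocortical-connectivity comparison, directed strengths are averaged
across the two directions of each pair; rostral/intermediate/caudal RSP
collapse to a single RSP and ALM is excluded (the external table does not
resolve them), reducing the design's 27 pathway pairs to 19. Pairwise
group comparisons use t or Wilcoxon tests with Bonferroni correction,
the family being the set of comparisons in one call; printed
`mean ± SD, n` summaries can be re-tested with `t_from_summary()` (Welch;
identical to the pooled statistic at equal group sizes). Which of t versus
Wilcoxon the original used per panel is unstated, so both are exposed.

## Problem sizes and numerical choices

Default simulated studies (per-pathway counts from the packaged table,
two slices per level) run in seconds. Recovery checks that quantify
calibration accuracy use a boosted reference population (2,000 reference
neurons per slice, so the per-slice hull closely approaches the calibration
disc) and ≥2,000 module neurons, where the dorsal-shell fraction of a
70%-dorsal module is recovered within three percentage points; at the
table's native counts (~50–150 reference neurons per slice) the hull of the
closest 90% is slightly smaller than the disc and core fractions of
non-reference pathways bias down by a point or two. Otsu thresholding uses
256 levels; degenerate (constant) maps are an error, as is a polygon from
collinear points. Zero-denominator rates (no ipsilateral neurons, empty
masks, all-zero counts) are errors or `NA`s, never silent zeros.

## A worked example

```{r example, eval = FALSE}
library(clamap)

pw <- default_pathways(c("iRSP", "MOs", "ALM", "MOp"))
cp <- default_coprojection(pw, coproj_sets = c(`ALM;MOp` = 0.05,
                                               `MOs;iRSP` = 0.04))
sim <- generate_experiment(pw, cp, seed = 7)
cl <- classify_cells(sim$cells, ref_channel = "iRSP")
core_shell_proportions(cl$cells)

u <- uncorrected_counts(sim$cells, channels = names(pw))
pairwise_jaccard(u)
suppressWarnings(inclusion_exclusion(u))$union_count
```

The same stages run end to end via `run_pipeline(pipeline_config(...))`,
which adds density maps, module masks, overlaps, association tables and a
machine-readable summary; `inst/cli/clamap.R` wraps the same functions for
shell use.

## Known limitations

* The core polygon is convex; a genuinely concave claustrum core would be
  over-covered (an alpha-shape variant would need a shape parameter the
  source method does not provide).
* The dorsal/ventral split at the registered centroid height is a
  convention; no anatomical landmark pins it.
* The detectability model treats tracers as independent Bernoulli
  reporters; competition or synergy at co-injected sites would bias
  capture–recapture estimates.
* Categorical rostrocaudal levels (rostral/intermediate/caudal) follow the
  slice-group design; no continuous rostrocaudal coordinate is modeled.
* Uncorrected-count tables from manual counting can be mildly
  inconsistent under Möbius inversion; the package surfaces, rather than
  repairs, such inconsistencies.
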