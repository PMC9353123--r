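---
title: "Methods: simulating sampling strategies for nutritional performance landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating sampling strategies for nutritional performance landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscape)
```

## The problem

Geometric Framework (GF) experiments estimate how a life-history trait
responds to the joint intake of two nutrients, here protein (P) and
carbohydrate (C) in g/L. The classical design crosses a handful of
*nutritional rails* (fixed P:C ratios) with total-concentration levels.
Because all anchors sit on rays through the origin bounded by the extreme
rails, the sampled set is a triangular fan: the high-P, high-C corner and
the regions beyond the extreme rails are never measured. A performance
landscape interpolated from such anchors is an *extrapolation* over much
of the space, and any property read off it there — peak shape, peak
area, curvature — inherits that extrapolation error.

`nutriscape` quantifies this by simulation: choose a known ("baseline")
landscape, sample it under a design, reconstruct the landscape from the
samples alone, and compare reconstruction to truth. Everything is
deterministic given seeds, so the comparison is exactly reproducible.

## Designs

Four strategies, all returning anchors inside a rectangular
`nutrient_space()`:

* **gf** — one anchor per (ratio, concentration) pair. Defaults are six
  rails (P:C = 1:16 ... 2:1) by four concentrations (25–100 g/L), 24
  anchors. These defaults are a deliberately *typical* classical design,
  not a replica of any specific study; pass your own rails and
  concentrations to mimic a given dataset.
* **hexagonal** — centers of a flat-top hexagonal tiling. Every pair of
  adjacent anchors is exactly 2r apart (r the hexagon apothem): rows are
  spaced √3·r, odd rows offset by r, so in-row and cross-row neighbour
  distances coincide. If each anchor contributes a circular Gaussian
  "certainty" about the trait surface (`certainty_kernel()`), hexagonal
  packing is the densest way to tile certainty over the space — the
  motivating argument for this design.
* **square** — centers of a square tiling; same-row/column neighbours at
  2r, diagonal neighbours at 2√2·r.
* **random** — uniform draws over the rectangle, seeded.

**Exact anchor counts.** A lattice clipped to a rectangle rarely contains
a requested count exactly. The generators bisect on the apothem for the
largest r whose clipped lattice holds at least `resolution` centers, then
drop the excess points farthest from the space centroid. This keeps
counts exactly comparable across strategies (len(points) == resolution,
which the tests rely on) at the cost of slightly ragged lattice edges;
interior spacing is untouched, which is why the nearest-neighbour
invariants still hold for every retained point. `resolution = 1`
degenerates to the space centroid by convention.

Rails at the axes are supported: ratio `0` is the pure-carbohydrate rail
(p = 0, where a lifespan-like trait peaks), `Inf` the pure-protein rail.

## Baseline landscapes

The baseline (the "truth" unknown in a real experiment) is a dense
regular grid, default spacing 4 g/L over [0, 100]², i.e. 26 × 26 = 676
nodes. Two sources:

* `baseline_from_observations()` — fit a lightly smoothed thin-plate
  spline (λ = 0.001) to an observed diet–trait table and evaluate it on
  the grid, extending beyond the observed region. The smoother is
  pluggable; the default is deterministic, which we prefer over stochastic
  learners for a reference surface.
* `scenario_landscape()` — analytic archetypes (below).

The default space is [0, 100]² g/L. Published data-driven workflows
extend the grid beyond the observed diets; when building a space from a
table we therefore add a configurable margin (default 10%) around the
data extent.

## Synthetic scenarios: the stated world

Three archetypes emulate the qualitative structure of the classic
*Drosophila* lifespan/reproduction traits:

| scenario             | peak (p, c) g/L | peak P:C | shape                      |
|----------------------|-----------------|----------|----------------------------|
| `lifespan_like`      | (0, 75)         | ~0:1     | half-Gaussian, max on the C axis |
| `lifetime_eggs_like` | (25, 75)        | 1:3      | interior Gaussian          |
| `daily_eggs_like`    | (30, 60)        | 1:2      | interior Gaussian          |

Surfaces are bivariate Gaussians A·exp(−Q/2) with amplitude A = 100
(arbitrary trait units), σ\_p = σ\_c = 20 g/L, ρ = 0 and zero noise by
default; `scenario_diet_table()` adds i.i.d. Gaussian measurement noise
only to simulated anchor measurements. The σ = 20 choice makes the peak
occupy a realistic fraction of the space (the 95th-percentile region is a
disc of radius ≈ 13 g/L) while leaving low-response margins, resembling
the ridge-and-peak structure of empirical landscapes. What the generator
does **not** emulate: multi-modal surfaces, holes from lethal diet
regions, heteroscedastic or non-Gaussian measurement error, and intake
(as opposed to fixed-ratio) data. A green recovery test therefore
establishes that the pipeline recovers *smooth unimodal* structure, not
that it is robust to those complications.

## Thin-plate spline reconstruction

`tps_fit()` solves the classical 2-D smoothing TPS: kernel
φ(d) = d² log d (natural log, φ(0) = 0) plus an affine part, with side
conditions Σw = Σw·p = Σw·c = 0, via the QR null space of the affine
basis (the test suite checks it against an independent dense solve of the
bordered system).

Numerical choices worth stating:

* **Coordinate standardization.** Anchors are mapped to the unit square
  of their bounding box before kernel evaluation; the affine part is
  reported back on the g/L scale. This removes the dependence of λ's
  meaning on measurement units.
* **λ convention.** The ridge enters as λ itself on the kernel diagonal
  of the standardized system: K + λI. An n·λ convention was tried first
  and rejected: on unit-square coordinates the kernel entries are O(0.1),
  so n·λ = 2.5–12.5 at the resolutions of interest flattens the surface
  to half its amplitude and displaces the peak — at which point λ = 0.05
  no longer means "mild smoothing", contradicting the behaviour the
  default is meant to encode. Under K + λI, λ = 0.05 reproduces a
  50-anchor Gaussian peak with ~10% maximum error and an unmoved argmax.
  Reference implementations rescale λ internally in yet other ways, so
  numeric λ values are comparable within this package, not across
  software; since the strategy comparison holds λ fixed for all designs,
  none of its conclusions depend on the convention.
* **Degeneracies.** Collinear anchor sets are rejected; anchors closer
  than 1e-9 are merged by averaging, with a message. λ = 0 interpolates;
  affine data are reproduced exactly for every λ (the kernel part is
  orthogonal to affine trends).

## Peak estimation

The peak algorithm used in the antecedent literature is external to this
package; we use a transparent stand-in, clearly labelled and pluggable:

* **Region**: all grid nodes at or above the q-th quantile (default
  0.95) of the landscape's values, ties included, never empty.
* **Truncation at the anchor hull.** A reconstruction is only supported
  inside the convex hull of its anchors; outside it the spline is
  extrapolating. When a hull is supplied (the default inside
  `run_comparison()`), both the quantile and the region are computed over
  hull-interior nodes only. This is what makes the GF design's peak
  estimates *smaller and truncated* for interior peaks — its hull clips
  the region — and it is the mechanism behind the headline area
  contrast. Regions are also always clipped at the space boundary; no
  area beyond the bounds is counted.
* **Centroid and ratio**: unweighted mean of region coordinates;
  P:C = centroid\_p / centroid\_c (undefined at c ≈ 0).
* **Boundary flag**: raised when the centroid *or the region's
  maximum-value node* lies within one grid spacing of a space edge, or —
  when a hull is in use — when the maximum-value node lies within one
  spacing of the hull boundary. The centroid-only rule was found to
  under-flag: a boundary peak's region is one-sidedly truncated, which
  pulls the centroid inward by more than one spacing.
* **Ellipse**: principal-component ellipse of the region coordinates,
  semi-axes k√Λᵢ with k = 2, chosen because it recovers the full radius
  of a uniform disc (covariance R²/4) and ≈95% of the mass of
  Gaussian-shaped regions; area = πab. Whether historical analyses used
  covariance or extreme-point ellipses is not documented; covariance is
  more stable on discretized regions and is recorded in the output
  metadata. Sub-3-point or collinear regions give zero area with a
  warning.

## Accuracy profile

`topological_profile()` pairs the two landscapes node by node (identical
grids enforced), takes the per-node distance |Δvalue| — for profile
points sharing their x coordinate the 2-D Euclidean distance reduces to
exactly this — places each node at x = P·C, and averages within 100
equal-width x bins (right-open, last closed; empty bins reported with
n = 0, single-point bins with SD 0). High P·C is the upper-right region
reachable only by designs that sample beyond the rail fan, which is why
the GF profile diverges there.

## The simulated experiment

`run_comparison()` chains, per (trait, strategy, resolution): design →
anchor values → TPS reconstruction (λ = 0.05, 4 g/L grid) → hull-truncated
peak estimate → profile against the baseline. Per-bin profiles are
reported for the highest requested resolution (default 250), where
reconstruction is most favourable to every strategy.

Anchor values come from one of two sources:

* `value_source = "quadratic"` (default): fit the full second-order
  response surface (1, P, C, P², C², PC) to the baseline grid by OLS and
  evaluate it at the anchors. This mirrors the gridded-baseline protocol,
  where off-grid anchor coordinates need a predictor, and matches the
  standard GF analysis model.
* `value_source = "surface"`: evaluate the baseline's own analytic
  surface at the anchors — literally running the simulated experiment
  against the truth.

The distinction matters for *parameter recovery*: a full-domain OLS
quadratic fitted to a localized Gaussian bump displaces the stationary
point toward the domain centre (for the 1:3 archetype it even yields a
saddle), so recovery of the *scenario's* true ratio is only a
well-posed question under the surface route, which is what the recovery
tests use. For *strategy contrasts* the route is immaterial — all
strategies see the same values — and both reproduce the same directions.

The GF strategy keeps its configured rails × concentrations at every
"resolution" (its count is fixed by the crossing, as in real designs);
the space-filling strategies match the requested count exactly.

Replicate variation for the seeded contrast tests comes from the random
design's seed plus measurement noise `noise_sd = 2` (2% of amplitude) on
anchor values — without it the gf/hex/square arms are fully
deterministic and "10 replicates" would be one measurement repeated.

## What the tests establish

* Geometry: exact counts; hexagonal NN distance single-valued at 2r;
  square neighbour set {2r, 2√2·r}; GF hull coverage < 1.
* TPS: interpolation at λ = 0, exact affine reproduction for all λ,
  equivalence with an independent bordered-system solve, RSS
  non-decreasing and bending energy non-increasing in λ.
* Recovery (noiseless, surface route, hull-truncated peaks): hex and
  square at resolutions 50 and 250 recover interior peak ratios within
  10% (deterministically); the random strategy is tested on its median
  over seeds 1–10, its natural summary; lifespan-like peaks raise the
  boundary flag.
* Contrast (10 seeded replicates, noise 2%): GF peak area below every
  alternative's, and GF top-decile P·C profile error above hexagonal's,
  each in ≥9 of 10 replicates. Observed margins are large (area ~170 vs
  ~460 (g/L)²; top-decile error ~40–60 vs ~1–3 trait units).

## Known limitations

* The quantile peak region is a stand-in for the dedicated peak
  algorithm of the antecedent framework; `peak_region()` is pluggable.
* Two nutrients only; no simplex designs for 3+.
* No intake-data simulation (anchors as realized intakes), no rules of
  compromise, no landscapes with holes.
* No optimality criteria (D-optimal etc.) beyond the four strategies.
* λ is fixed, not selected by cross-validation; that is faithful to the
  comparison being simulated, not a recommendation for data analysis.
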