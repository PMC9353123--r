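# nutriscape

Simulation toolkit for evaluating **experimental designs in the Geometric
Framework for nutrition (GF)**.

GF experiments map a life-history trait (lifespan, egg production, ...)
over a two-nutrient space — protein and carbohydrate concentration, in
g/L — producing a *performance landscape* whose peaks, valleys and shape
carry the biology. The standard GF design places diets along *nutritional
rails* (rays of fixed P:C ratio) crossed with total-concentration levels,
which concentrates anchor points in a triangular wedge and leaves the rest
of the space to extrapolation. `nutriscape` asks, by simulation, what that
choice costs: it generates designs under four strategies, simulates the
experiment against a known baseline landscape, reconstructs the landscape
from the sampled anchors, and measures what each strategy recovers.

For whom: nutritional ecologists planning fixed-ratio GF experiments, and
methodologists studying response-surface sampling.

## The model in brief

- **Designs.** `gf_design()` (rails × concentrations: for ratio ρ = P/C
  and total t, the anchor is p = tρ/(1+ρ), c = t/(1+ρ));
  `hex_design()` (centers of a hexagonal tiling, every neighbour pair
  exactly 2r apart — the densest circle packing, so maximal area covered
  per anchor); `square_design()` (square tiling, neighbour distances 2r
  and 2√2·r); `random_design()` (uniform). Lattice designs return
  *exactly* the requested number of anchors (see the vignette).
- **Reconstruction.** `reconstruct_landscape()` fits a smoothed
  thin-plate spline f(x) = a₀ + a₁p + a₂c + Σᵢ wᵢ φ(‖x − xᵢ‖), with
  φ(d) = d² log d, ridge λ (default 0.05) on the kernel diagonal of the
  unit-square-standardized system, and evaluates it on a dense 4 g/L
  grid.
- **Peak estimation.** `estimate_peak()` takes the ≥95th-percentile
  region of the reconstruction (optionally truncated to the design's
  anchor hull — estimates are only supported where anchors exist),
  reports its centroid P:C ratio, a boundary/truncation flag, and the
  area πab of the principal-component ellipse with semi-axes k√Λᵢ
  (k = 2).
- **Accuracy.** `topological_profile()` collapses baseline vs.
  reconstruction to x = P·C with per-point distance |Δvalue|, binned into
  100 equal-width bins — reconstruction error as a function of how
  nutrient-rich the diet region is.
- **Synthetic truth.** `make_scenario()` provides three archetypes:
  `lifespan_like` (boundary peak, P:C ~ 0:1), `lifetime_eggs_like`
  (interior peak, P:C = 1:3), `daily_eggs_like` (interior peak,
  P:C = 1:2), as bivariate Gaussian surfaces with known peaks.

## Worked example

Simulate a 50-diet hexagonal experiment on a trait peaking at
P:C = 1:2, reconstruct the landscape, and estimate the peak:

```r
library(nutriscape)
space    <- nutrient_space(0, 100, 0, 100)   # g/L protein x carbohydrate
design   <- hex_design(space, resolution = 50)
design
#> <hexagonal design: 50 anchor points, apothem r = 7.619 g/L>

scenario <- make_scenario("daily_eggs_like", space)
scenario
#> <scenario 'daily_eggs_like': peak (30, 60) g/L (P:C = 0.5), amplitude 100,
#>  sigma (20, 20), rho 0, noise_sd 0>

measurements <- scenario_diet_table(scenario, design)
anchors <- data.frame(p = measurements$p, c = measurements$c,
                      value = measurements$daily_eggs_like)
recon <- reconstruct_landscape(anchors, space, spacing = 4, lambda = 0.05,
                               trait = "daily_eggs_like")
recon
#> <landscape 'daily_eggs_like': 676 grid points, spacing 4 g/L,
#>  value range [-6.923, 88.64]>

peak <- estimate_peak(recon, quantile = 0.95, hull = design_hull(design))
peak
#> <peak estimate: centroid (29.93, 60.44) g/L, P:C = 0.4951,
#>  area 444.4 (g/L)^2>

baseline <- scenario_landscape(scenario, space)
attr(topological_profile(baseline, recon, 100), "overall_mean_dist")
#> [1] 2.188622
```

Reading the output: 50 hexagonally packed diets recover the true peak
ratio 0.5 to 1% (0.4951); the reconstruction's mean absolute error
against the true surface is ~2.2 trait units on a 0–100 scale. Running
`run_comparison()` over all four strategies shows the contrast the
package exists to quantify: the standard GF design finds the same ratio
but a peak area of ~170 (g/L)² versus ~460 for the space-filling
designs — its peak estimate is truncated at the rail fan's hull — and
its profile error in the high-P·C region is an order of magnitude
larger.

## Command line

```sh
Rscript inst/cli/nutriscape design --strategy hex --resolution 50 --out design.csv
Rscript inst/cli/nutriscape synth --scenario daily_eggs_like --resolution 50 --out diet.csv
Rscript inst/cli/nutriscape reconstruct --table diet.csv --lambda 0.05 --out recon.csv
Rscript inst/cli/nutriscape peaks --landscape recon.csv --out peaks.csv
Rscript inst/cli/nutriscape compare --scenarios daily_eggs_like \
    --strategies gf,hexagonal,square,random --resolutions 30,50,250 --out-dir out/
```

All outputs are plain CSV with a `#`-comment metadata header (tool
version, config hash, seeds); identical invocations produce byte-identical
files.

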