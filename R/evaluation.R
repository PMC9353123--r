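#' @title Reconstruction accuracy and strategy comparison
#' @name evaluation
NULL

#' Binned topological profile of reconstruction error
#'
#' Reduces the 3-D comparison of two landscapes sharing the same grid to a
#' 1-D profile: each grid point is placed on the x-axis at its
#' protein-times-carbohydrate product \eqn{P \cdot C} (a proxy for total
#' nutrient "richness"; high values are the upper-right interaction
#' region), and the per-point distance is the Euclidean distance between
#' the paired profile points, which for points paired at identical
#' coordinates reduces to the absolute value difference.  The x-axis is
#' split into `n_bins` equal-width bins (right-open, last bin closed) and
#' the mean and SD of the distances are reported per bin.
#'
#' @param baseline,reconstructed Two `landscape`s on the identical grid.
#' @param n_bins Number of bins, default 100.
#' @return Data.frame with columns `bin_index` (0-based), `x_lo`, `x_hi`,
#'   `n_points`, `mean_dist`, `sd_dist` (0 for single-point bins, NA for
#'   empty ones); overall mean distance in `attr(, "overall_mean_dist")`.
#' @export
topological_profile <- function(baseline, reconstructed, n_bins = 100) {
  stopifnot(n_bins >= 1)
  b <- as.data.frame(baseline)[, c("p", "c", "value")]
  r <- as.data.frame(reconstructed)[, c("p", "c", "value")]
  ob <- order(b$p, b$c); or <- order(r$p, r$c)
  b <- b[ob, ]; r <- r[or, ]
  if (nrow(b) != nrow(r) ||
      any(abs(b$p - r$p) > 1e-9) || any(abs(b$c - r$c) > 1e-9)) {
    mism <- if (nrow(b) != nrow(r)) 1L else
      which(abs(b$p - r$p) > 1e-9 | abs(b$c - r$c) > 1e-9)[1L]
    stop(sprintf("landscape grids do not match (first mismatch near (%g, %g))",
                 b$p[mism], b$c[mism]))
  }
  x <- b$p * b$c
  dist <- abs(b$value - r$value)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  if (n_bins == 1L || min(x) == max(x)) {
    idx <- rep(1L, length(x))
    breaks <- c(min(x), max(x))
    n_bins <- 1L
  } else {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  }
  out <- data.frame(bin_index = 0:(n_bins - 1L),
                    x_lo = breaks[-length(breaks)],
                    x_hi = breaks[-1L])
  out$n_points <- tabulate(idx, nbins = n_bins)
  out$mean_dist <- as.numeric(tapply(dist, factor(idx, levels = 1:n_bins),
                                     mean))
  sdv <- as.numeric(tapply(dist, factor(idx, levels = 1:n_bins), stats::sd))
  sdv[out$n_points == 1L] <- 0
  out$sd_dist <- sdv
  attr(out, "overall_mean_dist") <- mean(dist)
  out
}

default_gf_rails <- c(1/16, 1/8, 1/4, 1/2, 1, 2)

make_design <- function(strategy, space, resolution, seed = 1L,
                        gf_ratios = default_gf_rails,
                        gf_concentrations = c(25, 50, 75, 100)) {
  switch(strategy,
         gf = gf_design(space, gf_ratios, gf_concentrations),
         hexagonal = , hex = hex_design(space, resolution),
         square = , sq = square_design(space, resolution),
         random = random_design(space, resolution, seed = seed),
         stop(sprintf("unknown strategy '%s'", strategy)))
}

#' Run the full sampling-strategy comparison
#'
#' For every (baseline trait, strategy, resolution) combination, simulates
#' the experiment end to end: sample the design, assign trait values at
#' the anchors, reconstruct the landscape with a smoothed thin-plate
#' spline, estimate the peak (region truncated to the design's anchor
#' hull), and profile the reconstruction against the baseline.
#'
#' Anchor values come either from the full quadratic response surface
#' fitted to the baseline grid (`value_source = "quadratic"`, the gridded-
#' baseline protocol) or directly from the baseline's own surface function
#' when one is attached (`value_source = "surface"`, exact simulated
#' measurements; falls back to an interpolating spline of the grid).
#'
#' The standard GF strategy always uses its configured rails and
#' concentrations — its anchor count is fixed by the crossing, not by
#' `resolutions` — and is run once per resolution label for comparability.
#'
#' @param baselines Named list of baseline `landscape`s (names = traits).
#' @param strategies Subset of c("gf", "hexagonal", "square", "random").
#' @param resolutions Anchor counts for the space-filling strategies;
#'   default c(30, 50, 250).
#' @param spacing,lambda,quantile,ellipse_k,n_bins Pipeline parameters
#'   (defaults 4 g/L, 0.05, 0.95, 2, 100).
#' @param value_source "quadratic" or "surface" (see Details).
#' @param noise_sd Measurement noise SD added to anchor values.
#' @param seed Integer; seeds the random design and the noise draws.
#' @param clip_to_hull Truncate peak regions at the design's anchor hull
#'   (default TRUE).
#' @param gf_ratios,gf_concentrations Rails and concentration levels for
#'   the GF strategy.
#' @return List of class `comparison_result`: `summary` (one row per
#'   combination: pc_ratio, boundary_flag, peak_area, overall_mean_dist),
#'   `profiles` (per-bin rows for the highest resolution), and `peaks`
#'   (the `peak_estimate` objects, named trait.strategy.resolution).
#' @export
run_comparison <- function(baselines,
                           strategies = c("gf", "hexagonal", "square", "random"),
                           resolutions = c(30, 50, 250),
                           spacing = 4, lambda = 0.05, quantile = 0.95,
                           ellipse_k = 2, n_bins = 100,
                           value_source = c("quadratic", "surface"),
                           noise_sd = 0, seed = 1L, clip_to_hull = TRUE,
                           gf_ratios = default_gf_rails,
                           gf_concentrations = c(25, 50, 75, 100)) {
  value_source <- match.arg(value_source)
  if (!is.list(baselines) || inherits(baselines, "landscape"))
    baselines <- list(trait = baselines)
  if (is.null(names(baselines)))
    names(baselines) <- vapply(baselines, attr, "", "trait")
  stopifnot(all(strategies %in% c("gf", "hexagonal", "square", "random")))
  summ <- list(); profs <- list(); peaks <- list()
  profile_res <- max(resolutions)
  for (trait in names(baselines)) {
    baseline <- baselines[[trait]]
    space <- attr(baseline, "space")
    surface <- if (value_source == "quadratic") {
      fit_quadratic_surface(baseline)
    } else {
      f <- attr(baseline, "surface_fun")
      if (is.null(f)) {
        m <- tps_fit(baseline[, c("p", "c")], baseline$value, lambda = 0.001)
        function(p, c) predict(m, data.frame(p = p, c = c))
      } else f
    }
    for (strategy in strategies) {
      for (res in resolutions) {
        des <- make_design(strategy, space, res, seed = seed,
                           gf_ratios = gf_ratios,
                           gf_concentrations = gf_concentrations)
        av <- sample_design_values(surface, des, noise_sd = noise_sd,
                                   seed = seed + res)
        recon <- reconstruct_landscape(av, space, spacing = spacing,
                                       lambda = lambda, trait = trait)
        hull <- if (clip_to_hull) design_hull(des) else NULL
        pk <- estimate_peak(recon, quantile = quantile, k = ellipse_k,
                            hull = hull, space = space)
        prof <- topological_profile(baseline, recon, n_bins = n_bins)
        tag <- paste(trait, strategy, res, sep = ".")
        peaks[[tag]] <- pk
        summ[[tag]] <- data.frame(
          trait = trait, strategy = strategy, resolution = res,
          n_points = nrow(des),
          pc_ratio = pk$pc_ratio, boundary_flag = pk$boundary_flag,
          peak_area = pk$area,
          overall_mean_dist = attr(prof, "overall_mean_dist"))
        if (res == profile_res) {
          prof$trait <- trait; prof$strategy <- strategy
          prof$resolution <- res
          profs[[tag]] <- prof
        }
      }
    }
  }
  structure(list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 profiles = do.call(rbind, c(profs, make.row.names = FALSE)),
                 peaks = peaks,
                 config = list(spacing = spacing, lambda = lambda,
                               quantile = quantile, ellipse_k = ellipse_k,
                               n_bins = n_bins, value_source = value_source,
                               noise_sd = noise_sd, seed = seed,
                               clip_to_hull = clip_to_hull)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<strategy comparison>\n")
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}
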