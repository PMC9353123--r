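#' @title Peak region, P:C ratio and ellipse area
#'
#' @description The peak of a reconstructed landscape is summarized in
#' three steps: (i) the peak region — all grid points whose value reaches a
#' high quantile of the landscape's values; (ii) the region centroid and
#' its protein-to-carbohydrate ratio, with a flag when the centroid hugs
#' the space boundary; (iii) an ellipse approximation of the region from
#' the principal components of its coordinates, whose area \eqn{\pi a b}
#' measures peak breadth.
#' @name peaks
NULL

#' Extract the peak region of a landscape
#'
#' Returns the grid points whose value is at or above the given quantile of
#' the landscape's values (ties at the threshold included; the maximum is
#' always in the region).  When `hull` is supplied — typically the convex
#' hull of the design's anchor points — both the value distribution and the
#' region are restricted to grid points inside it: peak estimates from a
#' reconstruction are only supported where anchor points exist, so the
#' region is truncated at that boundary.
#'
#' @param landscape A `landscape`.
#' @param quantile Threshold quantile in (0, 1); default 0.95.
#' @param hull Optional two-column matrix of convex-hull vertices
#'   (counter-clockwise), e.g. [design_hull()].
#' @return Data.frame of grid points (`p`, `c`, `value`) in the region,
#'   with the threshold in `attr(, "threshold")`.
#' @export
peak_region <- function(landscape, quantile = 0.95, hull = NULL) {
  stopifnot(quantile > 0, quantile < 1)
  pts <- as.data.frame(landscape)[, c("p", "c", "value")]
  if (!is.null(hull))
    pts <- pts[in_convex_hull(hull, pts$p, pts$c), , drop = FALSE]
  if (!nrow(pts)) stop("no grid points inside the supplied hull")
  thr <- stats::quantile(pts$value, quantile, names = FALSE)
  region <- pts[pts$value >= thr, , drop = FALSE]
  if (nrow(region) == nrow(pts))
    message("degenerate peak region: all landscape values tie at the threshold")
  rownames(region) <- NULL
  attr(region, "threshold") <- thr
  attr(region, "quantile") <- quantile
  region
}

#' Centroid and P:C ratio of a peak region
#'
#' The centroid is the unweighted mean of the region's grid coordinates;
#' the P:C ratio is `centroid_p / centroid_c`.  The boundary flag is raised
#' when the centroid — or, when the region carries values, its
#' maximum-value point — lies within one grid spacing of an edge of the
#' space: peaks on the boundary (e.g. a lifespan peak at P:C ~ 0:1) have
#' ill-conditioned ratio estimates and truncated shapes.  (The centroid of
#' a boundary-truncated region is pulled inward, so the centroid test
#' alone under-flags genuine boundary peaks.)
#'
#' @param region Data.frame of region points (from [peak_region()]).
#' @param spacing Grid spacing (g/L) used for the boundary test.
#' @param space Optional [nutrient_space()]; when missing, only proximity
#'   to the axes (p = 0 or c = 0) is tested.
#' @return List with `centroid` (named p, c), `pc_ratio` (NA when the
#'   centroid carbohydrate is ~0) and `boundary_flag`.
#' @export
peak_centroid_ratio <- function(region, spacing = 4, space = NULL) {
  stopifnot(nrow(region) >= 1L)
  ctr <- c(p = mean(region$p), c = mean(region$c))
  ratio <- if (ctr["c"] < 1e-12) NA_real_ else unname(ctr["p"] / ctr["c"])
  probes <- list(ctr)
  if ("value" %in% names(region)) {
    i <- which.max(region$value)
    probes <- c(probes, list(c(p = region$p[i], c = region$c[i])))
  }
  near_edge <- function(pt) {
    if (is.null(space))
      pt["p"] < spacing || pt["c"] < spacing
    else
      pt["p"] - space$p_min < spacing || space$p_max - pt["p"] < spacing ||
        pt["c"] - space$c_min < spacing || space$c_max - pt["c"] < spacing
  }
  near <- any(vapply(probes, near_edge, logical(1)))
  list(centroid = ctr, pc_ratio = ratio, boundary_flag = unname(near))
}

#' Ellipse approximation of a peak region
#'
#' Approximates the region by the ellipse centred at its centroid whose
#' axes follow the principal components of the region coordinates, with
#' semi-axes \eqn{k\sqrt{\Lambda_i}} for eigenvalues \eqn{\Lambda_i} of the
#' coordinate covariance.  The default `k = 2` recovers the full radius of
#' a uniform disc (covariance \eqn{R^2/4}) and covers ~95% of the mass of
#' Gaussian-shaped regions.  Degenerate regions (fewer than 3 points, or
#' collinear) yield zero area with a warning.
#'
#' @param region Data.frame of region points.
#' @param k Semi-axis scale factor, default 2.
#' @return List with `center`, `semi_axes` (a >= b, g/L), `angle`
#'   (radians, orientation of the major axis) and `area` \eqn{= \pi a b}
#'   in (g/L)^2.
#' @export
fit_peak_ellipse <- function(region, k = 2) {
  ctr <- c(p = mean(region$p), c = mean(region$c))
  if (nrow(region) < 3L) {
    warning("degenerate peak region (< 3 points): zero-area ellipse")
    return(list(center = ctr, semi_axes = c(a = 0, b = 0), angle = 0,
                area = 0))
  }
  S <- stats::cov(cbind(region$p, region$c))
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (ev[2L] < 1e-12 * max(ev[1L], 1)) {
    warning("degenerate (collinear) peak region: zero-area ellipse")
    return(list(center = ctr,
                semi_axes = c(a = k * sqrt(ev[1L]), b = 0),
                angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                area = 0))
  }
  a <- k * sqrt(ev[1L]); b <- k * sqrt(ev[2L])
  list(center = ctr, semi_axes = c(a = a, b = b),
       angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
       area = pi * a * b)
}

#' Full peak estimate for a landscape
#'
#' Convenience wrapper running [peak_region()], [peak_centroid_ratio()] and
#' [fit_peak_ellipse()] with one call.
#'
#' @inheritParams peak_region
#' @inheritParams fit_peak_ellipse
#' @param space Space for the boundary flag; defaults to the landscape's.
#' @return An object of class `peak_estimate`: list with `region`,
#'   `centroid`, `pc_ratio`, `boundary_flag`, `ellipse`, `area`,
#'   `quantile`.
#' @export
estimate_peak <- function(landscape, quantile = 0.95, k = 2, hull = NULL,
                          space = attr(landscape, "space")) {
  spacing <- attr(landscape, "spacing")
  region <- peak_region(landscape, quantile, hull = hull)
  cr <- peak_centroid_ratio(region, spacing = spacing, space = space)
  if (!cr$boundary_flag && !is.null(hull)) {
    # a peak whose maximum sits against the anchor-support boundary is
    # truncated even when that boundary lies inside the space
    i <- which.max(region$value)
    cr$boundary_flag <-
      dist_to_polygon(hull, region$p[i], region$c[i]) < spacing
  }
  ell <- fit_peak_ellipse(region, k = k)
  structure(list(region = region, centroid = cr$centroid,
                 pc_ratio = cr$pc_ratio, boundary_flag = cr$boundary_flag,
                 ellipse = ell, area = ell$area, quantile = quantile),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat(sprintf("<peak estimate: centroid (%.2f, %.2f) g/L, P:C = %.4g%s, area %.4g (g/L)^2>\n",
              x$centroid["p"], x$centroid["c"], x$pc_ratio,
              if (isTRUE(x$boundary_flag)) " [boundary]" else "",
              x$area))
  invisible(x)
}
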