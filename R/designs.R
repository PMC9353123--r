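#' @title Anchor-point designs over the nutrient space
#'
#' @description
#' Four sampling strategies are available for placing anchor points (diet
#' treatments) in a two-nutrient space: the standard Geometric Framework
#' design built from nutritional rails and diet concentrations
#' ([gf_design()]), and three space-filling alternatives — hexagonal
#' ([hex_design()]), square ([square_design()]) and uniform random
#' ([random_design()]) grids.
#'
#' A design is a data.frame with columns `p`, `c` (g/L) and, for GF designs,
#' `rail_ratio` and `concentration`; metadata (strategy, requested
#' resolution, cell apothem, seed) is carried in attributes.
#'
#' @name designs
NULL

new_design <- function(points, strategy, resolution, space,
                       cell_apothem = NA_real_, seed = NA_integer_) {
  if (!"rail_ratio" %in% names(points)) points$rail_ratio <- NA_real_
  if (!"concentration" %in% names(points)) points$concentration <- NA_real_
  rownames(points) <- NULL
  structure(points,
            class = c("nutri_design", "data.frame"),
            strategy = strategy, resolution = resolution, space = space,
            cell_apothem = cell_apothem, seed = seed)
}

#' @export
print.nutri_design <- function(x, ...) {
  cat(sprintf("<%s design: %d anchor points", attr(x, "strategy"), nrow(x)))
  if (is.finite(attr(x, "cell_apothem")))
    cat(sprintf(", apothem r = %.4g g/L", attr(x, "cell_apothem")))
  cat(">\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Standard Geometric Framework design (rails x concentrations)
#'
#' Places one anchor point at each combination of nutritional rail (fixed
#' P:C ratio, a ray from the origin) and total diet concentration.  For a
#' ratio \eqn{\rho = P/C} and concentration \eqn{t = P + C} the anchor is
#' \eqn{p = t\rho/(1+\rho)}, \eqn{c = t/(1+\rho)}.  The boundary rail of
#' pure carbohydrate is ratio 0 (p = 0); the pure-protein rail is `Inf`.
#'
#' @param space A [nutrient_space()].
#' @param ratios Numeric vector of P:C rail ratios (P/C); 0 and `Inf`
#'   denote the axes.
#' @param concentrations Numeric vector of total-nutrient levels (g/L).
#' @return A `nutri_design` with `rail_ratio` and `concentration` tags.
#' @examples
#' d <- gf_design(nutrient_space(), ratios = c(1/4, 1, 2),
#'                concentrations = c(40, 80))
#' nrow(d)  # 6
#' @export
gf_design <- function(space,
                      ratios = c(1/16, 1/8, 1/4, 1/2, 1, 2),
                      concentrations = c(25, 50, 75, 100)) {
  stopifnot(inherits(space, "nutrient_space"))
  if (any(ratios < 0) || anyNA(ratios)) stop("rail ratios must be >= 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  grid <- expand.grid(rail_ratio = ratios, concentration = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  rr <- grid$rail_ratio
  tt <- grid$concentration
  p <- ifelse(is.infinite(rr), tt, tt * rr / (1 + rr))
  c_ <- ifelse(is.infinite(rr), 0, tt / (1 + rr))
  bad <- !in_space(space, p, c_)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "rail ratio %g at concentration %g projects to (%.3g, %.3g), outside the space",
      rr[i], tt[i], p[i], c_[i]))
  }
  pts <- data.frame(p = p, c = c_, rail_ratio = rr, concentration = tt)
  pts <- drop_duplicate_points(pts)
  new_design(pts, "gf", nrow(pts), space)
}

drop_duplicate_points <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 2L) return(pts)
  key <- paste(round(pts$p / tol), round(pts$c / tol))
  dup <- duplicated(key)
  if (any(dup)) {
    message(sprintf("dropping %d duplicate anchor point(s)", sum(dup)))
    pts <- pts[!dup, , drop = FALSE]
  }
  pts
}

# Count and enumerate centers of a flat-top hexagonal tiling with apothem r,
# clipped to the space. Rows r*sqrt(3) apart; odd rows offset by r; first
# row anchored at (p_min + r, c_min + r). Nearest-neighbour distance is 2r.
hex_lattice <- function(space, r, eps = 1e-9) {
  ys <- seq(space$c_min + r, space$c_max + eps, by = sqrt(3) * r)
  out <- vector("list", length(ys))
  for (j in seq_along(ys)) {
    x0 <- space$p_min + r + ((j - 1L) %% 2L) * r
    if (x0 > space$p_max + eps) next
    xs <- seq(x0, space$p_max + eps, by = 2 * r)
    out[[j]] <- cbind(p = xs, c = rep(ys[j], length(xs)))
  }
  do.call(rbind, out)
}

square_lattice <- function(space, r, eps = 1e-9) {
  xs <- seq(space$p_min + r, space$p_max + eps, by = 2 * r)
  ys <- seq(space$c_min + r, space$c_max + eps, by = 2 * r)
  as.matrix(expand.grid(p = xs, c = ys, KEEP.OUT.ATTRS = FALSE))
}

# Largest apothem whose clipped lattice holds at least n centers, found by
# bisection (the count is a nonincreasing step function of r); the excess
# centers farthest from the space centroid are then dropped so that the
# returned design has exactly n points.
exact_count_lattice <- function(space, n, lattice_fun) {
  ctr <- space_centroid(space)
  lo <- min(space_width(space), space_height(space)) / (4 * (sqrt(n) + 2))
  hi <- min(space_width(space), space_height(space)) / 2
  count_at <- function(r) {
    m <- lattice_fun(space, r)
    if (is.null(m)) 0L else nrow(m)
  }
  while (count_at(lo) < n) lo <- lo / 2   # safety: ensure feasible bracket
  for (i in 1:70) {
    mid <- (lo + hi) / 2
    if (count_at(mid) >= n) lo <- mid else hi <- mid
  }
  r <- lo
  m <- lattice_fun(space, r)
  d2 <- (m[, "p"] - ctr["p"])^2 + (m[, "c"] - ctr["c"])^2
  keep <- order(d2)[seq_len(n)]
  m <- m[sort(keep), , drop = FALSE]
  list(points = data.frame(p = m[, "p"], c = m[, "c"]), apothem = r)
}

#' Hexagonal space-filling design
#'
#' Anchor points sit at the centers of a hexagonal tiling of the space.
#' The hexagonal grid is the densest circle packing of the plane, so for a
#' fixed Gaussian "certainty" radius around each anchor it covers the most
#' area per anchor point; every pair of adjacent anchors is exactly
#' \eqn{2r} apart, with r the hexagon apothem.
#'
#' The tiling is computed at the largest apothem that yields at least
#' `resolution` clipped centers and the excess points farthest from the
#' space centroid are dropped, so the returned design has exactly
#' `resolution` points (see the package vignette).
#'
#' @param space A [nutrient_space()].
#' @param resolution Number of anchor points (>= 1).
#' @return A `nutri_design`; the apothem is in `attr(, "cell_apothem")`.
#' @examples
#' d <- hex_design(nutrient_space(), 30)
#' nrow(d)  # 30
#' @export
hex_design <- function(space, resolution) {
  check_resolution(resolution)
  if (resolution == 1L)
    return(new_design(as.data.frame(as.list(space_centroid(space))),
                      "hexagonal", 1L, space))
  fit <- exact_count_lattice(space, resolution, hex_lattice)
  new_design(fit$points, "hexagonal", resolution, space,
             cell_apothem = fit$apothem)
}

#' Square space-filling design
#'
#' Anchor points at the centers of a square tiling: neighbours in the same
#' row or column are \eqn{2r} apart, diagonal neighbours \eqn{2\sqrt{2}r},
#' with r the square apothem (half the side).  Exact-count behaviour as in
#' [hex_design()].
#'
#' @inheritParams hex_design
#' @return A `nutri_design`.
#' @export
square_design <- function(space, resolution) {
  check_resolution(resolution)
  if (resolution == 1L)
    return(new_design(as.data.frame(as.list(space_centroid(space))),
                      "square", 1L, space))
  fit <- exact_count_lattice(space, resolution, square_lattice)
  new_design(fit$points, "square", resolution, space,
             cell_apothem = fit$apothem)
}

#' Uniform random design
#'
#' Draws `resolution` anchor points uniformly over the space rectangle.
#' Reproducible: the RNG state is seeded with `seed` and restored on exit.
#'
#' @inheritParams hex_design
#' @param seed Integer seed.
#' @return A `nutri_design`.
#' @export
random_design <- function(space, resolution, seed = 1L) {
  check_resolution(resolution)
  pts <- with_seed(seed, {
    data.frame(p = stats::runif(resolution, space$p_min, space$p_max),
               c = stats::runif(resolution, space$c_min, space$c_max))
  })
  new_design(pts, "random", resolution, space, seed = as.integer(seed))
}

check_resolution <- function(resolution) {
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      resolution < 1 || resolution != round(resolution))
    stop("resolution must be a positive integer")
}

# Evaluate thunk under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gaussian certainty kernel around an anchor point
#'
#' The knowledge ("certainty") that an anchor point contributes about the
#' trait surface is modelled as a bivariate Gaussian density centred on the
#' anchor: \deqn{\eta(x, y) = C e^{-[(x-x_0)^2/(2\sigma_X^2) +
#' (y-y_0)^2/(2\sigma_Y^2)]}.}  With equal variances this is the circular
#' kernel whose densest packing motivates the hexagonal design.
#'
#' @param amplitude Kernel amplitude C (trait units).
#' @param x0,y0 Anchor coordinates (g/L).
#' @param sigma_x2,sigma_y2 Variances (g/L)^2, both > 0.
#' @return An object of class `certainty_kernel`.
#' @export
certainty_kernel <- function(amplitude, x0, y0, sigma_x2, sigma_y2 = sigma_x2) {
  stopifnot(sigma_x2 > 0, sigma_y2 > 0)
  structure(list(amplitude = amplitude, x0 = x0, y0 = y0,
                 sigma_x2 = sigma_x2, sigma_y2 = sigma_y2),
            class = "certainty_kernel")
}

#' @rdname certainty_kernel
#' @param kernel A `certainty_kernel`.
#' @param x,y Coordinates at which to evaluate the density (vectorized).
#' @export
certainty_density <- function(kernel, x, y) {
  stopifnot(inherits(kernel, "certainty_kernel"))
  kernel$amplitude * exp(-((x - kernel$x0)^2 / (2 * kernel$sigma_x2) +
                           (y - kernel$y0)^2 / (2 * kernel$sigma_y2)))
}

#' Design diagnostics: spacing and coverage
#'
#' Summarizes how a design fills its space: the distribution of
#' nearest-neighbour distances between anchors and the fraction of the
#' space area covered by the convex hull of the anchors.  A standard GF
#' design leaves the high-P, high-C region outside its hull (coverage < 1),
#' which is the root of its reconstruction error there.
#'
#' @param design A `nutri_design`.
#' @param space A [nutrient_space()]; defaults to the design's own space.
#' @return A list with `nn_distances` (one per anchor), `coverage`
#'   (hull area / space area, in \[0, 1\]) and `hull` (the hull vertices).
#' @export
design_diagnostics <- function(design, space = attr(design, "space")) {
  stopifnot(inherits(design, "nutri_design"))
  if (nrow(design) < 3L)
    stop("need at least 3 anchor points for hull diagnostics")
  m <- cbind(design$p, design$c)
  dm <- as.matrix(stats::dist(m))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  hull_idx <- grDevices::chull(m)
  hull <- m[hull_idx, , drop = FALSE]
  cov <- polygon_area(hull) / space_area(space)
  list(nn_distances = nn, coverage = min(cov, 1), hull = hull)
}

# Shoelace formula; vertices in hull order.
polygon_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Convex hull of a design's anchor points
#'
#' @param design A `nutri_design` (or any data.frame with `p`, `c`).
#' @return A two-column matrix of hull vertices in counter-clockwise order.
#' @export
design_hull <- function(design) {
  m <- cbind(design$p, design$c)
  idx <- grDevices::chull(m)       # chull returns clockwise order
  m[rev(idx), , drop = FALSE]
}

# Distance from a point to the boundary of a polygon (vertex matrix).
dist_to_polygon <- function(poly, p, c) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1L]; ay <- poly[i, 2L]
    ex <- poly[j, 1L] - ax; ey <- poly[j, 2L] - ay
    t <- ((p - ax) * ex + (c - ay) * ey) / (ex * ex + ey * ey)
    t <- min(max(t, 0), 1)
    dmin <- min(dmin, sqrt((p - (ax + t * ex))^2 + (c - (ay + t * ey))^2))
  }
  dmin
}

# Points-in-convex-polygon test; vertices counter-clockwise.
in_convex_hull <- function(hull, p, c, tol = 1e-9) {
  n <- nrow(hull)
  if (n < 3L) return(rep(FALSE, length(p)))
  inside <- rep(TRUE, length(p))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- hull[j, 1L] - hull[i, 1L]
    ey <- hull[j, 2L] - hull[i, 2L]
    cross <- ex * (c - hull[i, 2L]) - ey * (p - hull[i, 1L])
    inside <- inside & cross >= -tol * (abs(ex) + abs(ey) + 1)
  }
  inside
}
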