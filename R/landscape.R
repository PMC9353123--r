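#' @title Performance landscapes on a dense grid
#'
#' @description A landscape stores one trait's value at every node of a
#' regular grid over a nutrient space: the package's stand-in for the "true"
#' (baseline) performance surface, and the container for every TPS
#' reconstruction.
#' @name landscape
NULL

new_landscape <- function(grid, values, trait, spacing, space, meta = list()) {
  stopifnot(nrow(grid) == length(values))
  if (any(!is.finite(values)))
    stop("landscape values must all be finite")
  l <- data.frame(p = grid$p, c = grid$c, value = values)
  structure(l, class = c("landscape", "data.frame"),
            trait = trait, spacing = spacing, space = space, meta = meta)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape '%s': %d grid points, spacing %g g/L, value range [%.4g, %.4g]>\n",
              attr(x, "trait"), nrow(x), attr(x, "spacing"),
              min(x$value), max(x$value)))
  meta <- attr(x, "meta")
  if (length(meta))
    cat("  meta:", paste(names(meta), unlist(meta), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Build a baseline landscape from observed diet-trait records
#'
#' Fits a smooth predictor (by default a lightly smoothed thin-plate
#' spline, `lambda = 0.001`) to observed (protein, carbohydrate, trait)
#' records and evaluates it on the dense grid, extending to the full space
#' even beyond the observed region.  This produces the "true" baseline
#' surface that reconstructions from sparser designs are judged against.
#'
#' @param table Data.frame with columns `p`, `c` and the trait column.
#' @param space A [nutrient_space()].
#' @param spacing Grid spacing (g/L), default 4.
#' @param trait Name of the trait column in `table`.
#' @param lambda Smoothing for the baseline spline.
#' @param predictor Either "tps" (default) or a function
#'   `f(table, trait)` returning a prediction function `g(p, c)`.
#' @return A `landscape`.
#' @export
baseline_from_observations <- function(table, space, spacing = 4,
                                       trait = setdiff(names(table), c("p", "c"))[1L],
                                       lambda = 0.001, predictor = "tps") {
  stopifnot(is.data.frame(table), all(c("p", "c", trait) %in% names(table)))
  ok <- is.finite(table[[trait]])
  table <- table[ok, , drop = FALSE]
  loc <- unique(round(cbind(table$p, table$c), 9))
  if (nrow(loc) < 6L)
    stop("need at least 6 distinct (p, c) locations to build a baseline")
  grid <- make_grid(space, spacing)
  if (is.function(predictor)) {
    g <- predictor(table, trait)
    vals <- g(grid$p, grid$c)
  } else {
    fit <- tps_fit(table[, c("p", "c")], table[[trait]], lambda = lambda)
    vals <- predict(fit, grid)
  }
  if (any(vals < 0))
    message(sprintf("baseline extrapolates below zero at %d grid point(s); values kept",
                    sum(vals < 0)))
  new_landscape(grid, vals, trait, spacing, space,
                meta = list(predictor = if (is.function(predictor)) "custom" else "tps",
                            lambda_baseline = lambda))
}

#' Fit a full quadratic response surface to a landscape
#'
#' Ordinary least squares of the landscape values on
#' \eqn{1, P, C, P^2, C^2, PC} — the standard second-order response-surface
#' model of GF analyses.  Used to assign trait values to anchor points when
#' simulating an experiment against a gridded baseline.
#'
#' @param landscape A `landscape` (or data.frame with `p`, `c`, `value`).
#' @return A `quad_surface`: named coefficient vector
#'   (b0, p, c, p2, c2, pc) with a [predict][predict.quad_surface] method.
#' @export
fit_quadratic_surface <- function(landscape) {
  stopifnot(all(c("p", "c", "value") %in% names(landscape)))
  if (nrow(landscape) < 6L) stop("need at least 6 points")
  X <- quad_design_matrix(landscape$p, landscape$c)
  qx <- qr(X)
  if (qx$rank < 6L)
    stop("quadratic design matrix is singular (points do not span both axes)")
  beta <- qr.coef(qx, landscape$value)
  structure(stats::setNames(beta, c("b0", "p", "c", "p2", "c2", "pc")),
            class = "quad_surface")
}

quad_design_matrix <- function(p, c) {
  cbind(1, p, c, p^2, c^2, p * c)
}

#' @export
print.quad_surface <- function(x, ...) {
  cat("<quadratic surface> value = b0 + b1 P + b2 C + b3 P^2 + b4 C^2 + b5 PC\n")
  print(unclass(x))
  invisible(x)
}

#' Predict from a quadratic surface
#'
#' @param object A `quad_surface`.
#' @param newdata Data.frame with columns `p` and `c`.
#' @param ... Unused.
#' @export
predict.quad_surface <- function(object, newdata, ...) {
  drop(quad_design_matrix(newdata$p, newdata$c) %*% unclass(object))
}

# Stationary point of the quadratic; NULL when the Hessian is singular.
quad_stationary_point <- function(surface) {
  b <- unclass(surface)
  H <- matrix(c(2 * b["p2"], b["pc"], b["pc"], 2 * b["c2"]), 2L)
  if (abs(det(H)) < 1e-14) return(NULL)
  s <- solve(H, -c(b["p"], b["c"]))
  c(p = s[1L], c = s[2L])
}

#' Simulate trait measurements at design anchor points
#'
#' Evaluates a surface at each anchor of a design and adds i.i.d. Gaussian
#' measurement noise — the in-silico equivalent of running the feeding
#' experiment.  With `noise_sd = 0` (the default) the surface values are
#' returned exactly.
#'
#' @param surface A `quad_surface`, a `tps_model`, or a function `f(p, c)`.
#' @param design A `nutri_design`.
#' @param noise_sd Standard deviation of measurement noise (trait units).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return Data.frame with anchor columns plus `value`.
#' @export
sample_design_values <- function(surface, design, noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  vals <- eval_surface(surface, design$p, design$c)
  if (noise_sd > 0)
    vals <- vals + with_seed(seed, stats::rnorm(length(vals), 0, noise_sd))
  out <- as.data.frame(design)
  out$value <- vals
  attr(out, "strategy") <- attr(design, "strategy")
  attr(out, "resolution") <- attr(design, "resolution")
  out
}

eval_surface <- function(surface, p, c) {
  if (is.function(surface)) return(surface(p, c))
  predict(surface, data.frame(p = p, c = c))
}
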