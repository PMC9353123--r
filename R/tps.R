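#' @title Smoothed thin-plate splines in two dimensions
#'
#' @description Landscape reconstruction from anchor values uses the
#' classical 2-D thin-plate spline: radial kernel
#' \eqn{\phi(d) = d^2 \log d} (with \eqn{\phi(0) = 0}) plus an affine part,
#' with a ridge penalty \eqn{\lambda} on the kernel diagonal.  At
#' \eqn{\lambda = 0} the spline interpolates the anchors; larger
#' \eqn{\lambda} trades anchor fidelity for bending energy.
#'
#' Coordinates are standardized to the unit square of the anchor bounding
#' box before kernel evaluation, so the meaning of \eqn{\lambda} does not
#' depend on the g/L scale of the space; the affine part is reported on the
#' original scale.  Note this convention differs from implementations that
#' rescale \eqn{\lambda} internally, so a given numeric \eqn{\lambda} is
#' comparable across designs here but not necessarily across software.
#'
#' @name tps
NULL

tps_kernel <- function(d) {
  k <- d * d * log(d)
  k[d == 0] <- 0
  k
}

#' Fit a smoothed thin-plate spline
#'
#' Solves the standard bordered system
#' \deqn{(K + \lambda I)w + Pa = v, \qquad P^T w = 0,}
#' where \eqn{K_{ij} = \phi(\|x_i - x_j\|)} on standardized coordinates and
#' \eqn{P = [1\; p\; c]}.  The side conditions \eqn{\sum w_i = \sum w_i p_i
#' = \sum w_i c_i = 0} make the kernel part orthogonal to affine trends, so
#' affine data are reproduced exactly for every \eqn{\lambda}.  The solver
#' absorbs the constraints through the QR null space of \eqn{P} rather than
#' solving the bordered matrix directly.
#'
#' @param points Data.frame (or 2-col matrix) of anchor coordinates `p`, `c`.
#' @param values Trait values at the anchors.
#' @param lambda Smoothing parameter, >= 0; default 0.05.
#' @return A `tps_model` with elements `anchors`, `weights`, `affine`
#'   (original-scale a0, a1, a2), `lambda`, and the coordinate transform.
#' @export
tps_fit <- function(points, values, lambda = 0.05) {
  stopifnot(lambda >= 0)
  pts <- as.data.frame(points)
  if (!all(c("p", "c") %in% names(pts)))
    names(pts)[1:2] <- c("p", "c")
  stopifnot(nrow(pts) == length(values))
  merged <- merge_near_duplicates(pts$p, pts$c, values)
  p <- merged$p; cc <- merged$c; v <- merged$value
  n <- length(v)
  if (n < 4L) stop("need at least 4 anchor points")
  # standardize to the unit square of the anchor bounding box
  sp <- max(p) - min(p); sc <- max(cc) - min(cc)
  if (sp <= 0 || sc <= 0) stop("anchor points are collinear (zero extent)")
  p0 <- min(p); c0 <- min(cc)
  u <- (p - p0) / sp; w_ <- (cc - c0) / sc
  P <- cbind(1, u, w_)
  if (qr(P)$rank < 3L) stop("anchor points are collinear")
  K <- tps_kernel(as.matrix(stats::dist(cbind(u, w_))))
  M <- K + diag(lambda, n)
  qrP <- qr(P)
  Q <- qr.Q(qrP, complete = TRUE)
  Q1 <- Q[, 1:3, drop = FALSE]
  Q2 <- Q[, -(1:3), drop = FALSE]
  R1 <- qr.R(qrP)
  gamma <- solve(crossprod(Q2, M %*% Q2), crossprod(Q2, v))
  w <- drop(Q2 %*% gamma)
  a_std <- drop(backsolve(R1, crossprod(Q1, v - M %*% w)))
  # affine part back on the original g/L scale
  a1 <- a_std[2L] / sp
  a2 <- a_std[3L] / sc
  a0 <- a_std[1L] - a1 * p0 - a2 * c0
  structure(list(anchors = data.frame(p = p, c = cc),
                 std = cbind(u = u, v = w_),
                 weights = w,
                 affine = c(a0 = a0, a1 = a1, a2 = a2),
                 lambda = lambda,
                 transform = c(p0 = p0, sp = sp, c0 = c0, sc = sc),
                 fitted = drop(K %*% w) + a_std[1L] + a_std[2L] * u +
                   a_std[3L] * w_,
                 values = v),
            class = "tps_model")
}

merge_near_duplicates <- function(p, c, v, tol = 1e-9) {
  key <- paste(round(p / tol), round(c / tol))
  if (!anyDuplicated(key))
    return(data.frame(p = p, c = c, value = v))
  message("merging near-duplicate anchors by averaging their values")
  agg <- stats::aggregate(data.frame(p = p, c = c, value = v),
                          by = list(key = key), FUN = mean)
  agg <- agg[order(match(agg$key, key)), ]
  data.frame(p = agg$p, c = agg$c, value = agg$value)
}

#' @export
print.tps_model <- function(x, ...) {
  cat(sprintf("<thin-plate spline: %d anchors, lambda = %g>\n",
              nrow(x$anchors), x$lambda))
  invisible(x)
}

#' Evaluate a thin-plate spline
#'
#' @param object A `tps_model`.
#' @param newdata Data.frame with columns `p`, `c`.
#' @param ... Unused.
#' @return Numeric vector of predicted trait values.
#' @export
predict.tps_model <- function(object, newdata, ...) {
  tr <- object$transform
  u <- (newdata$p - tr[["p0"]]) / tr[["sp"]]
  v <- (newdata$c - tr[["c0"]]) / tr[["sc"]]
  du <- outer(u, object$std[, "u"], "-")
  dv <- outer(v, object$std[, "v"], "-")
  K <- tps_kernel(sqrt(du * du + dv * dv))
  drop(K %*% object$weights) + object$affine[["a0"]] +
    object$affine[["a1"]] * newdata$p + object$affine[["a2"]] * newdata$c
}

#' @rdname predict.tps_model
#' @param model A `tps_model`.
#' @param coords Data.frame of `p`, `c` coordinates.
#' @export
tps_predict <- function(model, coords) predict(model, coords)

# Bending energy w' K w of a fitted model (standardized coordinates).
tps_bending_energy <- function(model) {
  K <- tps_kernel(as.matrix(stats::dist(model$std)))
  drop(crossprod(model$weights, K %*% model$weights))
}

#' Reconstruct a landscape from anchor values
#'
#' Fits a thin-plate spline (default \eqn{\lambda = 0.05}) to
#' (anchor, value) records and evaluates it on the dense grid over the
#' space — step (iii) of the simulated experiment.  The grid extends over
#' the whole space, so for designs that cover only part of it (standard
#' GF) the evaluation is an extrapolation beyond the anchor hull.
#'
#' @param anchor_values Data.frame with columns `p`, `c`, `value`
#'   (e.g. from [sample_design_values()]).
#' @param space A [nutrient_space()].
#' @param spacing Grid spacing (g/L), default 4.
#' @param lambda Smoothing parameter, default 0.05.
#' @param trait Trait label for the output landscape.
#' @return A `landscape`; `attr(, "meta")` records lambda and, when
#'   `anchor_values` is a design sample, its strategy and resolution.
#' @export
reconstruct_landscape <- function(anchor_values, space, spacing = 4,
                                  lambda = 0.05, trait = "trait") {
  fit <- tps_fit(anchor_values[, c("p", "c")], anchor_values$value,
                 lambda = lambda)
  grid <- make_grid(space, spacing)
  vals <- predict(fit, grid)
  meta <- list(lambda = lambda,
               strategy = attr(anchor_values, "strategy"),
               resolution = attr(anchor_values, "resolution"))
  l <- new_landscape(grid, vals, trait, spacing, space,
                     meta = meta[!vapply(meta, is.null, logical(1))])
  attr(l, "model") <- fit
  l
}
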