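#' Define a rectangular two-nutrient space
#'
#' The nutritional space is the Cartesian plane spanned by the concentrations
#' of two nutrients, here protein (P) and carbohydrate (C), both in g/L.
#' All designs, landscapes and peak estimates in this package live inside
#' such a rectangle.
#'
#' @param p_min,p_max Protein concentration bounds (g/L).
#' @param c_min,c_max Carbohydrate concentration bounds (g/L).
#' @return An object of class `nutrient_space`.
#' @examples
#' sp <- nutrient_space(0, 100, 0, 100)
#' sp
#' @export
nutrient_space <- function(p_min = 0, p_max = 100, c_min = 0, c_max = 100) {
  stopifnot(is.numeric(p_min), is.numeric(p_max), is.numeric(c_min),
            is.numeric(c_max))
  if (p_min < 0 || c_min < 0)
    stop("nutrient concentrations cannot be negative")
  if (p_min >= p_max || c_min >= c_max)
    stop("bounds must satisfy p_min < p_max and c_min < c_max")
  structure(
    list(p_min = p_min, p_max = p_max, c_min = c_min, c_max = c_max),
    class = "nutrient_space"
  )
}

#' @export
print.nutrient_space <- function(x, ...) {
  cat(sprintf("Nutrient space: P in [%g, %g] g/L, C in [%g, %g] g/L\n",
              x$p_min, x$p_max, x$c_min, x$c_max))
  invisible(x)
}

space_width  <- function(space) space$p_max - space$p_min
space_height <- function(space) space$c_max - space$c_min
space_area   <- function(space) space_width(space) * space_height(space)

space_centroid <- function(space) {
  c(p = (space$p_min + space$p_max) / 2, c = (space$c_min + space$c_max) / 2)
}

#' Test whether points lie inside a nutrient space
#'
#' @param space A `nutrient_space`.
#' @param p,c Numeric vectors of coordinates (g/L), recycled to a common
#'   length.
#' @param tol Numeric tolerance for boundary points.
#' @return Logical vector.
#' @export
in_space <- function(space, p, c, tol = 1e-9) {
  p >= space$p_min - tol & p <= space$p_max + tol &
    c >= space$c_min - tol & c <= space$c_max + tol
}

#' Build a dense regular grid over a nutrient space
#'
#' The grid is closed at both ends: when a side length is an exact multiple
#' of `spacing`, both boundary rows/columns are included.  The 4 g/L default
#' spacing gives the dense lattice on which baseline and reconstructed
#' landscapes are compared.
#'
#' @param space A `nutrient_space`.
#' @param spacing Distance between adjacent grid points (g/L).
#' @return A data.frame with columns `p` and `c`, row order column-major in
#'   `p` within `c`.
#' @examples
#' nrow(make_grid(nutrient_space(0, 8, 0, 8), 4))  # 9
#' @export
make_grid <- function(space, spacing = 4) {
  stopifnot(inherits(space, "nutrient_space"), is.numeric(spacing),
            spacing > 0)
  if (spacing >= min(space_width(space), space_height(space)))
    stop("spacing must be smaller than the shortest side of the space")
  ps <- seq(space$p_min, space$p_max, by = spacing)
  cs <- seq(space$c_min, space$c_max, by = spacing)
  g <- expand.grid(p = ps, c = cs, KEEP.OUT.ATTRS = FALSE)
  attr(g, "spacing") <- spacing
  attr(g, "space") <- space
  g
}
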