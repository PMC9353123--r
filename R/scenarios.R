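#' @title Synthetic trait scenarios
#'
#' @description Three archetypal trait landscapes drive the package's
#' simulations, mirroring the qualitative shapes of classic
#' lifespan/reproduction data in *Drosophila*:
#' \itemize{
#'   \item `lifespan_like` — a boundary peak on the carbohydrate axis
#'     (P:C ~ 0:1), modelled as a half-Gaussian truncated at p = 0;
#'   \item `lifetime_eggs_like` — an interior peak at P:C = 1:3;
#'   \item `daily_eggs_like` — an interior peak at P:C = 1:2.
#' }
#' Surfaces are bivariate Gaussians \eqn{A\exp(-Q/2)} with
#' \eqn{Q = \frac{1}{1-\rho^2}\left[\frac{dp^2}{\sigma_p^2} -
#' \frac{2\rho\, dp\, dc}{\sigma_p \sigma_c} +
#' \frac{dc^2}{\sigma_c^2}\right]}, evaluated noiselessly on the grid;
#' measurement noise only enters simulated anchor tables.
#' @name scenarios
NULL

scenario_defaults <- list(
  lifespan_like      = list(peak_p = 0,  peak_c = 75),
  lifetime_eggs_like = list(peak_p = 25, peak_c = 75),
  daily_eggs_like    = list(peak_p = 30, peak_c = 60)
)

#' Create a synthetic trait scenario
#'
#' @param name One of "lifespan_like", "lifetime_eggs_like",
#'   "daily_eggs_like" or "custom".
#' @param space A [nutrient_space()] the peak must lie in.
#' @param overrides Named list overriding any field (peak_p, peak_c,
#'   amplitude, sigma_p, sigma_c, rho, noise_sd, seed); "custom" requires
#'   at least peak_p and peak_c.
#' @return An object of class `scenario`.
#' @examples
#' sc <- make_scenario("daily_eggs_like", nutrient_space())
#' sc$peak_p / sc$peak_c  # 0.5
#' @export
make_scenario <- function(name, space = nutrient_space(), overrides = list()) {
  known <- c(names(scenario_defaults), "custom")
  if (!name %in% known)
    stop(sprintf("unknown scenario '%s'; expected one of %s",
                 name, paste(known, collapse = ", ")))
  sc <- list(name = name, amplitude = 100, sigma_p = 20, sigma_c = 20,
             rho = 0, noise_sd = 0, seed = 1L)
  if (name != "custom") sc <- utils::modifyList(sc, scenario_defaults[[name]])
  sc <- utils::modifyList(sc, as.list(overrides))
  if (is.null(sc$peak_p) || is.null(sc$peak_c))
    stop("custom scenarios require peak_p and peak_c")
  stopifnot(sc$amplitude > 0, abs(sc$rho) < 1, sc$sigma_p > 0,
            sc$sigma_c > 0, sc$noise_sd >= 0)
  if (!in_space(space, sc$peak_p, sc$peak_c))
    stop("scenario peak lies outside the nutrient space")
  structure(sc, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': peak (%g, %g) g/L (P:C = %.4g), amplitude %g, sigma (%g, %g), rho %g, noise_sd %g>\n",
              x$name, x$peak_p, x$peak_c,
              if (x$peak_c > 0) x$peak_p / x$peak_c else Inf,
              x$amplitude, x$sigma_p, x$sigma_c, x$rho, x$noise_sd))
  invisible(x)
}

#' True surface function of a scenario
#'
#' @param scenario A `scenario`.
#' @return A function `f(p, c)` returning noiseless trait values.
#' @export
scenario_surface <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  force(scenario)
  function(p, c) {
    dp <- (p - scenario$peak_p) / scenario$sigma_p
    dc <- (c - scenario$peak_c) / scenario$sigma_c
    q <- (dp^2 - 2 * scenario$rho * dp * dc + dc^2) / (1 - scenario$rho^2)
    scenario$amplitude * exp(-q / 2)
  }
}

#' Noiseless baseline landscape of a scenario
#'
#' Evaluates the scenario's Gaussian surface on the dense grid.  For
#' `lifespan_like` the peak sits at p = 0, so the restriction to the space
#' is a half-Gaussian whose maximum lies exactly on the boundary.
#'
#' @param scenario A `scenario`.
#' @param space A [nutrient_space()].
#' @param spacing Grid spacing (g/L), default 4.
#' @return A `landscape` with the surface function attached as
#'   `attr(, "surface_fun")`.
#' @export
scenario_landscape <- function(scenario, space = nutrient_space(),
                               spacing = 4) {
  f <- scenario_surface(scenario)
  grid <- make_grid(space, spacing)
  l <- new_landscape(grid, f(grid$p, grid$c), scenario$name, spacing, space,
                     meta = list(scenario = scenario$name))
  attr(l, "surface_fun") <- f
  attr(l, "scenario") <- scenario
  l
}

#' Simulated diet-trait table for a design under a scenario
#'
#' One row per anchor point with trait value equal to the scenario surface
#' plus Gaussian measurement noise (`scenario$noise_sd`, seeded by
#' `scenario$seed`) — an emulated fixed-ratio feeding experiment.
#'
#' @param scenario A `scenario`.
#' @param design A `nutri_design`.
#' @return Data.frame with the anchor columns plus one trait column named
#'   after the scenario.
#' @export
scenario_diet_table <- function(scenario, design) {
  f <- scenario_surface(scenario)
  av <- sample_design_values(f, design, noise_sd = scenario$noise_sd,
                             seed = scenario$seed)
  names(av)[names(av) == "value"] <- scenario$name
  av
}
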