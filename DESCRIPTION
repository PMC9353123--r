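Package: nutriscape
Title: Sampling-Strategy Evaluation for Nutritional Performance Landscapes
Version: 0.1.0
Authors@R: person("nutriscape", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Simulation toolkit for experimental design in the Geometric
    Framework for nutrition. Generates anchor-point designs over a
    two-nutrient (protein by carbohydrate) space under four strategies
    (standard rails-and-concentrations, hexagonal, square, and random
    grids), reconstructs trait performance landscapes from sampled anchor
    values with smoothed thin-plate splines, estimates peak regions,
    protein-to-carbohydrate ratios and peak ellipse areas, and quantifies
    reconstruction accuracy against a known baseline landscape with a
    binned topological profile.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    grDevices,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
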