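test_that("GF design places one anchor per rail x concentration on its rail", {
  ratios <- c(1/16, 1/8, 1/4, 1/2, 1, 2)
  concs <- c(25, 50, 75, 100)
  d <- gf_design(sp100, ratios, concs)
  expect_equal(nrow(d), 24L)
  # brute-force rail check on all 24 anchors
  for (i in seq_len(nrow(d))) {
    expect_lt(abs(d$p[i] / d$c[i] - d$rail_ratio[i]), 1e-9)
    expect_lt(abs(d$p[i] + d$c[i] - d$concentration[i]), 1e-9)
  }
  expect_true(all(in_space(sp100, d$p, d$c)))
})

test_that("GF design handles single pair, axis rails and out-of-space errors", {
  d1 <- gf_design(sp100, ratios = 1, concentrations = 50)
  expect_equal(c(d1$p, d1$c), c(25, 25))
  dc <- gf_design(sp100, ratios = 0, concentrations = c(40, 80))
  expect_equal(dc$p, c(0, 0))
  expect_equal(dc$c, c(40, 80))
  dp <- gf_design(sp100, ratios = Inf, concentrations = 60)
  expect_equal(c(dp$p, dp$c), c(60, 0))
  expect_error(gf_design(sp100, ratios = 0, concentrations = 200),
               "ratio 0 at concentration 200")
})

test_that("multi-rail GF designs leave part of the space unexplored", {
  d <- gf_design(sp100)
  expect_lt(design_diagnostics(d)$coverage, 1)
})

test_that("hexagonal designs have exact counts and a single NN distance 2r", {
  expect_equal(unname(unlist(hex_design(sp100, 1)[1, c("p", "c")])),
               c(50, 50))
  for (n in c(30L, 50L, 250L)) {
    d <- hex_design(sp100, n)
    expect_equal(nrow(d), n)
    expect_true(all(in_space(sp100, d$p, d$c)))
    r <- attr(d, "cell_apothem")
    nn <- design_diagnostics(d)$nn_distances
    expect_lt(max(abs(nn - 2 * r)), 1e-6)
  }
})

test_that("square designs have neighbour distances {2r, 2*sqrt(2)*r}", {
  expect_equal(unname(unlist(square_design(sp100, 1)[1, c("p", "c")])),
               c(50, 50))
  d <- square_design(sp100, 25)   # complete 5x5 lattice, r = 10 feasible
  r <- attr(d, "cell_apothem")
  m <- cbind(d$p, d$c)
  dm <- as.matrix(dist(m))
  # interior point: nearest at 2r, next-nearest at 2*sqrt(2)*r
  ctr <- which.min((d$p - 50)^2 + (d$c - 50)^2)
  ds <- sort(dm[ctr, -ctr])
  expect_equal(unname(ds[1:4]), rep(2 * r, 4), tolerance = 1e-6)
  expect_equal(unname(ds[5:8]), rep(2 * sqrt(2) * r, 4), tolerance = 1e-6)
  # every location in the space is within sqrt(2)*r of some anchor
  fine <- expand.grid(p = seq(0, 100, 2.5), c = seq(0, 100, 2.5))
  mind <- apply(fine, 1L, function(q)
    min(sqrt((d$p - q[1])^2 + (d$c - q[2])^2)))
  expect_lt(max(mind), sqrt(2) * r + 1e-6)
})

test_that("square designs hit requested resolutions exactly", {
  for (n in c(30L, 50L, 250L)) {
    d <- square_design(sp100, n)
    expect_equal(nrow(d), n)
    expect_true(all(in_space(sp100, d$p, d$c)))
  }
})

test_that("random designs are uniform, bounded and seed-reproducible", {
  d1 <- random_design(sp100, 40, seed = 11)
  d2 <- random_design(sp100, 40, seed = 11)
  expect_identical(d1$p, d2$p)
  expect_identical(d1$c, d2$c)
  expect_false(identical(d1$p, random_design(sp100, 40, seed = 12)$p))
  expect_true(all(in_space(sp100, d1$p, d1$c)))
  big <- random_design(sp100, 10000, seed = 3)
  ctr <- c(50, 50)
  expect_lt(abs(mean(big$p) - ctr[1]) / ctr[1], 0.02)
  expect_lt(abs(mean(big$c) - ctr[2]) / ctr[2], 0.02)
})

test_that("random design leaves the caller's RNG stream untouched", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(random_design(sp100, 5, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("certainty density follows the Gaussian kernel formula", {
  k <- certainty_kernel(amplitude = 7, x0 = 30, y0 = 60, sigma_x2 = 16,
                        sigma_y2 = 25)
  expect_equal(certainty_density(k, 30, 60), 7)
  expect_equal(certainty_density(k, 30 + 4, 60), 7 * exp(-1/2))
  expect_equal(certainty_density(k, 30, 60 + 5), 7 * exp(-1/2))
  d <- 3.7
  expect_equal(certainty_density(k, 30 + d, 60),
               certainty_density(k, 30 - d, 60))
})

test_that("design diagnostics report coverage and spacing", {
  corners <- nutriscape:::new_design(
    data.frame(p = c(0, 100, 100, 0, 50), c = c(0, 0, 100, 100, 50)),
    "custom", 5L, sp100)
  expect_equal(design_diagnostics(corners, sp100)$coverage, 1.0)
  hexd <- hex_design(sp100, 30)
  nn <- design_diagnostics(hexd)$nn_distances
  expect_lt(diff(range(nn)), 1e-6)   # single-valued NN distribution
  two <- nutriscape:::new_design(data.frame(p = c(1, 2), c = c(1, 2)),
                                 "custom", 2L, sp100)
  expect_error(design_diagnostics(two), "at least 3")
})
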