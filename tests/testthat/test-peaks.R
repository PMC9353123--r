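gaussian_landscape <- function(peak_p = 48, peak_c = 48, sigma = 18,
                               space = sp100, spacing = 4) {
  g <- make_grid(space, spacing)
  v <- 100 * exp(-((g$p - peak_p)^2 + (g$c - peak_c)^2) / (2 * sigma^2))
  nutriscape:::new_landscape(g, v, "gauss", spacing, space)
}

test_that("peak region of a radial Gaussian is a disc around the maximum", {
  l <- gaussian_landscape()
  reg <- peak_region(l, 0.95)
  argmax <- l[which.max(l$value), ]
  ctr <- c(mean(reg$p), mean(reg$c))
  spacing <- attr(l, "spacing")
  expect_lt(sqrt((ctr[1] - argmax$p)^2 + (ctr[2] - argmax$c)^2), spacing)
  # region is the value-threshold superlevel set
  thr <- attr(reg, "threshold")
  expect_true(all(reg$value >= thr))
  expect_equal(nrow(reg), sum(l$value >= thr))
})

test_that("constant landscapes yield the whole-grid region with a message", {
  g <- make_grid(sp100, 20)
  flat <- nutriscape:::new_landscape(g, rep(1, nrow(g)), "flat", 20, sp100)
  expect_message(reg <- peak_region(flat, 0.95), "degenerate")
  expect_equal(nrow(reg), nrow(g))
})

test_that("regions nest with the quantile and areas shrink", {
  l <- gaussian_landscape()
  r90 <- peak_region(l, 0.90)
  r99 <- peak_region(l, 0.99)
  key <- function(r) paste(r$p, r$c)
  expect_true(all(key(r99) %in% key(r90)))
  areas <- vapply(c(0.8, 0.9, 0.95, 0.99), function(q)
    fit_peak_ellipse(peak_region(l, q))$area, 0)
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("peak region is invariant under row reordering", {
  l <- gaussian_landscape()
  shuffled <- l[sample(nrow(l)), ]
  attributes(shuffled)[c("spacing", "space")] <-
    attributes(l)[c("spacing", "space")]
  r1 <- peak_region(l, 0.95)
  r2 <- peak_region(shuffled, 0.95)
  key <- function(r) sort(paste(r$p, r$c))
  expect_identical(key(r1), key(r2))
})

test_that("centroid ratio arithmetic and symmetry", {
  one <- data.frame(p = 30, c = 60)
  cr <- peak_centroid_ratio(one, spacing = 4, space = sp100)
  expect_equal(cr$pc_ratio, 0.5)
  sym <- data.frame(p = c(40, 44, 48, 44), c = c(44, 40, 44, 48))
  expect_equal(peak_centroid_ratio(sym, 4, sp100)$pc_ratio, 1.0)
  near0 <- data.frame(p = c(0, 4), c = c(60, 64))
  expect_true(peak_centroid_ratio(near0, 4, sp100)$boundary_flag)
})

test_that("ellipse approximation matches known areas", {
  expect_warning(e1 <- fit_peak_ellipse(data.frame(p = 5, c = 5)),
                 "degenerate")
  expect_equal(e1$area, 0)
  # grid-discretized disc of radius R: k = 2 recovers pi R^2 within 5%
  R <- 20
  g <- expand.grid(p = seq(-40, 40, 1), c = seq(-40, 40, 1))
  disc <- g[g$p^2 + g$c^2 <= R^2, ]
  e <- fit_peak_ellipse(disc, k = 2)
  expect_lt(abs(e$area - pi * R^2) / (pi * R^2), 0.05)
  # similarity scaling: coordinates x s => area x s^2
  s <- 3.5
  es <- fit_peak_ellipse(data.frame(p = disc$p * s, c = disc$c * s), k = 2)
  expect_equal(es$area, e$area * s^2, tolerance = 1e-9)
  expect_warning(ec <- fit_peak_ellipse(data.frame(p = 1:5, c = 2 * (1:5))),
                 "collinear")
  expect_equal(ec$area, 0)
})

test_that("estimate_peak flags boundary peaks and truncation at the hull", {
  edge <- gaussian_landscape(peak_p = 0, peak_c = 60)
  pk <- estimate_peak(edge)
  expect_true(pk$boundary_flag)
  expect_lt(pk$pc_ratio, 0.15)
  interior <- gaussian_landscape()
  expect_false(estimate_peak(interior)$boundary_flag)
  # same peak becomes "boundary" when the support hull cuts off its maximum
  hull <- cbind(c(52, 100, 100, 52), c(0, 0, 100, 100))
  expect_true(estimate_peak(interior, hull = hull)$boundary_flag)
})
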