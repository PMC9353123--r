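scatter_points <- function(n, seed = 17) {
  set.seed(seed)
  data.frame(p = runif(n, 0, 100), c = runif(n, 0, 100))
}

test_that("lambda = 0 interpolates the anchors", {
  pts <- scatter_points(25)
  vals <- quad_fun(pts$p, pts$c)
  fit <- tps_fit(pts, vals, lambda = 0)
  expect_lt(max(abs(predict(fit, pts) - vals)), 1e-6)
})

test_that("affine data are reproduced exactly for every lambda", {
  pts <- scatter_points(20, seed = 3)
  vals <- 3 + 0.2 * pts$p - 0.1 * pts$c
  new <- scatter_points(15, seed = 4)
  for (lam in c(0, 0.05, 1)) {
    fit <- tps_fit(pts, vals, lambda = lam)
    expect_lt(max(abs(fit$weights)), 1e-8)
    expect_equal(predict(fit, new), 3 + 0.2 * new$p - 0.1 * new$c,
                 tolerance = 1e-8)
  }
})

test_that("fit matches the brute-force bordered-system solve", {
  for (n in c(6L, 10L)) {
    pts <- scatter_points(n, seed = n)
    vals <- quad_fun(pts$p, pts$c) + sin(pts$p / 10)
    fit <- tps_fit(pts, vals, lambda = 0.05)
    oracle <- tps_oracle(pts, vals, lambda = 0.05)
    expect_equal(fit$weights, unname(oracle$weights), tolerance = 1e-8)
    probe <- scatter_points(7, seed = 100 + n)
    expect_equal(predict(fit, probe), oracle$predict(probe$p, probe$c),
                 tolerance = 1e-8)
  }
})

test_that("orthogonality side conditions hold", {
  pts <- scatter_points(30, seed = 9)
  vals <- rnorm(30, quad_fun(pts$p, pts$c), 2)
  for (lam in c(0, 0.05, 0.5)) {
    fit <- tps_fit(pts, vals, lambda = lam)
    expect_lt(abs(sum(fit$weights)), 1e-8)
    expect_lt(abs(sum(fit$weights * pts$p)) / max(abs(pts$p)), 1e-8)
    expect_lt(abs(sum(fit$weights * pts$c)) / max(abs(pts$c)), 1e-8)
  }
})

test_that("RSS grows and bending energy shrinks with lambda", {
  pts <- scatter_points(20, seed = 21)
  vals <- rnorm(20, 50, 10)
  lams <- c(0, 0.01, 0.05, 0.5, 5)
  rss <- energy <- numeric(length(lams))
  for (i in seq_along(lams)) {
    fit <- tps_fit(pts, vals, lambda = lams[i])
    rss[i] <- sum((predict(fit, pts) - vals)^2)
    energy[i] <- nutriscape:::tps_bending_energy(fit)
  }
  expect_true(all(diff(rss) >= -1e-8))
  expect_true(all(diff(energy) <= 1e-8))
})

test_that("prediction agrees with direct formula evaluation", {
  pts <- scatter_points(12, seed = 31)
  vals <- quad_fun(pts$p, pts$c)
  fit <- tps_fit(pts, vals, lambda = 0.05)
  probe <- scatter_points(5, seed = 32)
  tr <- fit$transform
  u <- (probe$p - tr["p0"]) / tr["sp"]; v <- (probe$c - tr["c0"]) / tr["sc"]
  manual <- vapply(seq_len(5), function(i) {
    d <- sqrt((u[i] - fit$std[, "u"])^2 + (v[i] - fit$std[, "v"])^2)
    phi <- ifelse(d == 0, 0, d^2 * log(d))
    sum(fit$weights * phi) + fit$affine["a0"] +
      fit$affine["a1"] * probe$p[i] + fit$affine["a2"] * probe$c[i]
  }, 0)
  expect_equal(unname(predict(fit, probe)), unname(manual), tolerance = 1e-10)
})

test_that("the spline surface is continuous", {
  pts <- scatter_points(15, seed = 41)
  fit <- tps_fit(pts, quad_fun(pts$p, pts$c), lambda = 0.05)
  x0 <- data.frame(p = 33.3, c = 47.1)
  gaps <- vapply(c(1, 0.1, 0.01, 0.001), function(d)
    abs(predict(fit, x0) -
          predict(fit, data.frame(p = 33.3 + d, c = 47.1))), 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-2)
})

test_that("degenerate anchor sets are rejected and duplicates merged", {
  collin <- data.frame(p = 1:6 * 10, c = 1:6 * 10)
  expect_error(tps_fit(collin, rnorm(6), lambda = 0), "collinear")
  dup <- data.frame(p = c(10, 10, 50, 80, 20), c = c(20, 20, 60, 30, 90))
  expect_message(fit <- tps_fit(dup, c(1, 3, 5, 7, 9), lambda = 0),
                 "near-duplicate")
  expect_equal(nrow(fit$anchors), 4L)
  expect_equal(predict(fit, data.frame(p = 10, c = 20))[1], 2,
               tolerance = 1e-6)   # averaged value interpolated
})

test_that("reconstruction recovers a quadratic from dense anchors", {
  d <- square_design(sp100, 100)
  av <- sample_design_values(quad_fun, d)
  rec <- reconstruct_landscape(av, sp100, spacing = 4, lambda = 0.001,
                               trait = "quad")
  truth <- quad_fun(rec$p, rec$c)
  interior <- rec$p >= 10 & rec$p <= 90 & rec$c >= 10 & rec$c <= 90
  expect_lt(max(abs(rec$value - truth)[interior]) / max(abs(truth)), 0.01)
})

test_that("reconstruction records metadata and is deterministic", {
  d <- hex_design(sp100, 30)
  av <- sample_design_values(quad_fun, d)
  r1 <- reconstruct_landscape(av, sp100)
  r2 <- reconstruct_landscape(av, sp100)
  expect_equal(attr(r1, "meta")$lambda, 0.05)
  expect_equal(attr(r1, "meta")$strategy, "hexagonal")
  expect_identical(r1$value, r2$value)
})
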