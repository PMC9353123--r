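# Shared fixtures: the default 0-100 g/L space and a smooth positive
# quadratic used wherever an analytically known surface is needed.

sp100 <- nutrient_space(0, 100, 0, 100)

quad_coefs <- c(b0 = 50, p = 0.3, c = 0.4, p2 = -0.004, c2 = -0.003,
                pc = 0.002)

quad_fun <- function(p, c) {
  quad_coefs["b0"] + quad_coefs["p"] * p + quad_coefs["c"] * c +
    quad_coefs["p2"] * p^2 + quad_coefs["c2"] * c^2 + quad_coefs["pc"] * p * c
}

# scattered-but-covering observation set: 9x9 lattice over the space
obs_lattice <- function(space = sp100, n_side = 9) {
  expand.grid(p = seq(space$p_min, space$p_max, length.out = n_side),
              c = seq(space$c_min, space$c_max, length.out = n_side),
              KEEP.OUT.ATTRS = FALSE)
}

# independent dense solve of the bordered TPS system, using the package's
# documented convention (unit-square standardization, kernel d^2 log d,
# ridge lambda on the kernel diagonal) but a different solution path
tps_oracle <- function(pts, values, lambda) {
  p <- pts$p; cc <- pts$c
  phi <- function(d) ifelse(d == 0, 0, d^2 * log(d))
  sp_ <- max(p) - min(p); sc_ <- max(cc) - min(cc)
  u <- (p - min(p)) / sp_; v <- (cc - min(cc)) / sc_
  n <- length(values)
  K <- phi(as.matrix(dist(cbind(u, v))))
  P <- cbind(1, u, v)
  A <- rbind(cbind(K + diag(lambda, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  sol <- solve(A, c(values, 0, 0, 0))
  list(predict = function(newp, newc) {
    nu <- (newp - min(p)) / sp_; nv <- (newc - min(cc)) / sc_
    Kn <- phi(sqrt(outer(nu, u, "-")^2 + outer(nv, v, "-")^2))
    drop(Kn %*% sol[1:n]) + sol[n + 1] + sol[n + 2] * nu + sol[n + 3] * nv
  }, weights = sol[1:n])
}
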