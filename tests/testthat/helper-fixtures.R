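# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (double loops, literal formulas) and never call the code
# paths they check.

fixture_two_domain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_two_domain_structure(
      n_per_domain = 20, linker_length = 6, seed = 101)
    cache
  }
})

flatten_coords <- function(m) as.vector(t(m))
unflatten_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
cross_prod <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                               a[3] * b[1] - a[1] * b[3],
                               a[1] * b[2] - a[2] * b[1])

# Naive double-loop ANM Hessian assembly.
oracle_hessian <- function(xyz, cutoff = 15, k = 1) {
  n <- nrow(xyz)
  h <- matrix(0, 3 * n, 3 * n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    d <- xyz[j, ] - xyz[i, ]
    r2 <- sum(d^2)
    if (sqrt(r2) > cutoff) next
    blk <- -(k / r2) * outer(d, d)
    h[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- blk
    h[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] <-
      h[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)] - blk
  }
  h
}

# Literal term-by-term covariance overlap.
oracle_covariance_overlap <- function(la, va, lb, vb) {
  tot <- sum(la) + sum(lb)
  cross <- 0
  for (i in seq_along(la)) for (j in seq_along(lb)) {
    cross <- cross + sqrt(la[i] * lb[j]) * sum(va[, i] * vb[, j])^2
  }
  1 - sqrt(max(tot - 2 * cross, 0) / tot)
}

# Rotation matrix from Euler angles (z-y-z convention).
euler_rot <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

# Exhaustive coarse rotation grid + local refinement: the minimum RMSD of
# mobile onto reference over all proper rotations and translations.
oracle_min_rmsd <- function(mobile, reference) {
  pc <- sweep(mobile, 2, colMeans(mobile))
  qc <- sweep(reference, 2, colMeans(reference))
  obj <- function(p) {
    r <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((pc %*% t(r) - qc)^2)))
  }
  best <- NULL; best_v <- Inf
  for (a in seq(0, 2 * pi, length.out = 9)) for (b in seq(0, pi, length.out = 5))
    for (cc in seq(0, 2 * pi, length.out = 9)) {
      v <- obj(c(a, b, cc))
      if (v < best_v) { best_v <- v; best <- c(a, b, cc) }
    }
  opt <- stats::optim(best, obj, control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Random rigid transform applied to a coordinate matrix.
random_rigid <- function(xyz, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0.2, 2.8)
  kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  rot <- diag(3) + sin(ang) * kx + (1 - cos(ang)) * kx %*% kx
  xyz %*% t(rot) + matrix(rnorm(3, 0, 8), nrow(xyz), 3, byrow = TRUE)
}

# Thermodynamically consistent "harmonic bath" moment family: N oscillators
# whose interactions are scaled by lambda, so mean E1 = N kT / (2 lambda) and
# var E1 = N (kT / lambda)^2 / 2, with a small independent E2 component.
bath_mean_fn <- function(n_osc = 200, temperature = 300) {
  function(l) c(n_osc * kT(temperature) / (2 * l), 20 / l)
}
bath_cov_fn <- function(n_osc = 200, temperature = 300) {
  function(l) diag(c(n_osc * (kT(temperature) / l)^2 / 2, (2 / l)^2))
}

# Gaussian MC oracle for the expected Metropolis acceptance between two
# states of a fitted model, drawing directly from the model moments.
oracle_mc_acceptance <- function(model, s_a, s_b, n_draw = 1e6, seed = 1,
                                 temperature = 300) {
  mom <- function(s) confdyn:::state_moments(model, s)
  ma <- mom(s_a); mb <- mom(s_b)
  draw <- function(m) {
    ev <- eigen(m$cov, symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
    matrix(rnorm(2 * n_draw), n_draw, 2) %*% rt +
      matrix(m$mean, n_draw, 2, byrow = TRUE)
  }
  set.seed(seed)
  ea <- draw(ma); eb <- draw(mb)
  beta <- 1 / kT(temperature)
  delta <- beta * (s_a - s_b) *
    ((eb[, 1] - ea[, 1]) + (s_a + s_b) * (eb[, 2] - ea[, 2]))
  mean(pmin(1, exp(-delta)))
}
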