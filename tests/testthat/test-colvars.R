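test_that("membrane plane distance matches the planted geometry", {
  fx <- make_ring_and_membrane_fixtures(30, 45, plane_offset = 12,
                                        probe_distances = 40, seed = 5)
  mf <- membrane_frame(fx$phosphates)
  expect_equal(mf$plane_offset, 12, tolerance = 1e-12)
  # independent recompute of the offset
  expect_equal(mf$plane_offset, mean(fx$phosphates[, 3]), tolerance = 1e-12)
  expect_equal(plane_distance(fx$probes, mf), 40, tolerance = 1e-12)
  expect_equal(plane_distance(c(3, -7, 12), mf), 0, tolerance = 1e-12)
  expect_equal(plane_distance(c(0, 0, -28), mf), -40, tolerance = 1e-12)
  # leaflet split: second copy shifted 40 Angstrom below the first
  ph2 <- rbind(fx$phosphates, sweep(fx$phosphates, 2, c(0, 0, 40)))
  expect_equal(membrane_frame(ph2, leaflet = "lower")$plane_offset, -28,
               tolerance = 1e-9)
  expect_equal(membrane_frame(ph2, leaflet = "upper")$plane_offset, 12,
               tolerance = 1e-9)
})

test_that("tilt cosine equals an independent angle evaluation", {
  mf <- membrane_frame(cbind(runif(10), runif(10), 0))
  expect_equal(tilt_cosine(c(0, 0, 0), c(0, 0, 5), mf), 1.0)
  expect_equal(tilt_cosine(c(0, 0, 0), c(3, 4, 0), mf), 0.0)
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    v <- (b - a) / sqrt(sum((b - a)^2))
    expect_equal(tilt_cosine(a, b, mf), cos(acos(max(-1, min(1, v[3])))),
                 tolerance = 1e-12)
  }
  expect_error(tilt_cosine(c(1, 1, 1), c(1, 1, 1), mf), class = "confdyn_zero_vector")
})

test_that("contact count matches the naive switching-function sum", {
  a <- matrix(rnorm(15, sd = 3), 5, 3)
  b <- matrix(rnorm(12, sd = 3), 4, 3)
  naive <- 0
  for (i in 1:5) for (j in 1:4) {
    r <- sqrt(sum((a[i, ] - b[j, ])^2))
    x <- r / 6
    naive <- naive + if (abs(x - 1) < 1e-9) 0.5 else (1 - x^6) / (1 - x^12)
  }
  expect_equal(contact_count(a, b), naive, tolerance = 1e-12)
  # far pairs contribute nothing
  expect_lt(contact_count(a, b + 500), 1e-3)
  # r -> 0 limit is 1 per pair
  expect_warning(cc0 <- contact_count(matrix(0, 1, 3), matrix(0, 1, 3)))
  expect_equal(cc0, 1.0)
  # exactly at r0 the removable singularity evaluates to n/m
  p <- matrix(c(0, 0, 0), 1, 3); q <- matrix(c(6, 0, 0), 1, 3)
  expect_equal(contact_count(p, q, r0 = 6, n = 6, m = 12), 0.5, tolerance = 1e-9)
})

test_that("pair distances cover all modes and match centroid recomputation", {
  expect_equal(pair_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pair_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  set.seed(3)
  g <- matrix(rnorm(30), 10, 3)
  p <- c(2, -1, 4)
  expect_equal(pair_distance(p, g, mode = "atom-com"),
               sqrt(sum((p - colMeans(g))^2)), tolerance = 1e-12)
  g2 <- matrix(rnorm(15), 5, 3)
  expect_equal(pair_distance(g, g2, mode = "com-com"),
               sqrt(sum((colMeans(g) - colMeans(g2))^2)), tolerance = 1e-12)
})

test_that("ring polar angles recover planted orientations exactly", {
  # axis-aligned plants
  fx0 <- make_ring_and_membrane_fixtures(30, 0, rigid_transform = FALSE, seed = 1)
  out0 <- ring_polar_angles(fx0$frame_all, fx0$ring_idx, fx0$domain_sel,
                            reference = fx0$reference_all)
  expect_equal(out0$gamma, 30, tolerance = 1e-6)
  expect_equal(out0$theta, 0, tolerance = 1e-6)
  # 50 random orientations, with a random rigid transform applied to the frame
  set.seed(77)
  plants <- cbind(runif(50, 2, 88), runif(50, -179, 179))
  for (i in seq_len(nrow(plants))) {
    fx <- make_ring_and_membrane_fixtures(plants[i, 1], plants[i, 2],
                                          rigid_transform = TRUE, seed = 1000 + i)
    out <- ring_polar_angles(fx$frame_all, fx$ring_idx, fx$domain_sel,
                             reference = fx$reference_all)
    expect_equal(out$gamma, plants[i, 1], tolerance = 1e-6)
    expect_equal(out$theta, plants[i, 2], tolerance = 1e-6)
  }
  expect_error(ring_polar_angles(fx0$frame_all, c(1, 2), fx0$domain_sel,
                                 reference = fx0$reference_all),
               class = "confdyn_degenerate")
})

test_that("DRMSD is rigid-invariant, symmetric, and matches the double loop", {
  set.seed(4)
  xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  pairs <- t(combn(10, 2))
  expect_equal(drmsd(xyz, xyz, pairs), 0)
  expect_lt(drmsd(random_rigid(xyz, 5), xyz, pairs), 1e-9)
  pert <- xyz + matrix(rnorm(30, sd = 0.5), 10, 3)
  naive <- sqrt(mean(sapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    (sqrt(sum((pert[i, ] - pert[j, ])^2)) - sqrt(sum((xyz[i, ] - xyz[j, ])^2)))^2
  })))
  expect_equal(drmsd(pert, xyz, pairs), naive, tolerance = 1e-12)
  expect_equal(drmsd(pert, xyz, pairs), drmsd(xyz, pert, pairs), tolerance = 1e-12)
})

test_that("restraint energies match their defining formulas", {
  wall <- upper_wall_restraint(s0 = 2, kappa = 10, exponent = 2)
  expect_equal(restraint_energy(wall, 2), 0)
  expect_equal(restraint_energy(wall, 3), 10)
  expect_equal(restraint_energy(wall, c(0, 2.5)), c(0, 2.5))
  fun <- funnel_restraint(axis_point = c(0, 0, 0), axis_dir = c(0, 0, 1),
                          alpha = 30, r_cyl = 2, z_cc = 5, kappa = 3)
  # on-axis position: rho = 0, inside everywhere
  expect_equal(restraint_energy(fun, c(0, 0, -10)), 0)
  # inside the cylinder above z_cc
  expect_equal(restraint_energy(fun, c(1.5, 0, 8)), 0)
  # outside the cylinder above z_cc
  expect_equal(restraint_energy(fun, c(4, 0, 8)), 3 * (4 - 2)^2)
  # independent geometric evaluation on a 3D grid
  grid <- expand.grid(x = seq(-8, 8, 2), y = seq(-8, 8, 2), z = seq(-6, 10, 2))
  e <- restraint_energy(fun, as.matrix(grid))
  oracle <- apply(grid, 1, function(p) {
    z <- p[3]; rho <- sqrt(p[1]^2 + p[2]^2)
    rz <- if (z >= 5) 2 else 2 + (5 - z) * tan(30 * pi / 180)
    3 * max(0, rho - rz)^2
  })
  expect_equal(e, unname(oracle), tolerance = 1e-10)
  expect_true(all(e >= 0))
  expect_error(funnel_restraint(c(0, 0, 0), c(0, 0, 1), alpha = 95, r_cyl = 2,
                                z_cc = 5, kappa = 1), class = "confdyn_bad_input")
})

test_that("bound segmentation equals a naive scan", {
  out <- bound_segments(c(50, 30, 30, 50), threshold = 40)
  expect_equal(out$fraction, 0.5)
  expect_equal(nrow(out$segments), 1)
  expect_equal(out$segments$start, 2); expect_equal(out$segments$end, 3)
  none <- bound_segments(rep(50, 8))
  expect_equal(none$fraction, 0)
  expect_equal(nrow(none$segments), 0)
  set.seed(6)
  v <- runif(500, 0, 80)
  out2 <- bound_segments(v)
  # naive scan oracle
  b <- v < 40
  segs <- list(); i <- 1
  while (i <= length(b)) {
    if (b[i]) {
      j <- i
      while (j < length(b) && b[j + 1]) j <- j + 1
      segs[[length(segs) + 1]] <- c(i, j); i <- j + 1
    } else i <- i + 1
  }
  expect_equal(out2$fraction, mean(b))
  expect_equal(nrow(out2$segments), length(segs))
  expect_equal(out2$segments$start, sapply(segs, `[`, 1))
  expect_equal(out2$segments$end, sapply(segs, `[`, 2))
})

test_that("dihedrals match planar references and vector-algebra recomputation", {
  # planar cis (0) and trans (180)
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  expect_equal(torsion_series(cis, c(1, 2, 3, 4))$angle, 0, tolerance = 1e-9)
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  expect_equal(abs(torsion_series(trans, c(1, 2, 3, 4))$angle), 180, tolerance = 1e-9)
  set.seed(7)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    got <- torsion_series(p, c(1, 2, 3, 4))$angle
    # independent evaluation via projections onto the bond-normal plane
    b2 <- p[3, ] - p[2, ]
    u1 <- (p[1, ] - p[2, ]); u1 <- u1 - sum(u1 * b2) / sum(b2^2) * b2
    u2 <- (p[4, ] - p[3, ]); u2 <- u2 - sum(u2 * b2) / sum(b2^2) * b2
    ang <- acos(max(-1, min(1, sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2)))))
    sgn <- sign(sum(cross_prod(u1, u2) * b2))
    want <- -sgn * ang * 180 / pi
    expect_equal(abs(got), abs(want), tolerance = 1e-9)
    expect_equal(sign(got), sign(want))
  }
  expect_error(torsion_series(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
                              c(1, 2, 3, 4)), class = "confdyn_degenerate")
})

test_that("colvar tables round-trip through the FIELDS dialect", {
  d <- tibble::tibble(time = 1:5, dk = runif(5), gamma = runif(5, 0, 180))
  path <- tempfile()
  write_colvar(d, path)
  expect_match(readLines(path, n = 1), "^#! FIELDS time dk gamma")
  back <- read_colvar(path)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)
})
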