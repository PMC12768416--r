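test_that("PCA recovers planted variances and directions", {
  two <- fixture_two_domain()
  basis <- orthonormal_displacement_basis(two$structure, 3, seed = 55)
  pt <- make_planted_trajectory(two$structure, basis, c(9, 4, 1), 5000, seed = 56)
  pca <- fit_pca(pt$trajectory, n_components = 6)
  expect_equal(pca$values[1:3], c(9, 4, 1), tolerance = 0.1)
  for (k in 1:3)
    expect_gt(abs(vector_overlap(pca$vectors[, k], basis[, k])), 0.98)
  # total variance equals the covariance trace
  expect_equal(sum(pca$variance_fraction) * pca$total_variance,
               sum(pca$values), tolerance = 1e-8)
})

test_that("degenerate trajectories give rank-1 or zero PCA", {
  two <- fixture_two_domain()
  basis <- orthonormal_displacement_basis(two$structure, 1, seed = 3)
  pt <- make_planted_trajectory(two$structure, basis, 4, 200, seed = 4)
  pca <- fit_pca(pt$trajectory, n_components = 5)
  expect_equal(pca$variance_fraction[1], 1.0, tolerance = 1e-6)
  xyz <- coords(two$structure)
  static <- cd_trajectory(two$structure, list(xyz, xyz, xyz))
  pca0 <- fit_pca(static, n_components = 3)
  expect_true(all(pca0$values < 1e-12))
  expect_error(fit_pca(static, frames = 1), class = "confdyn_bad_input")
})

test_that("trajectory projection is linear with variance matching eigenvalues", {
  two <- fixture_two_domain()
  basis <- orthonormal_displacement_basis(two$structure, 2, seed = 7)
  pt <- make_planted_trajectory(two$structure, basis, c(6, 2), 5000, seed = 8)
  pca <- fit_pca(pt$trajectory, n_components = 4)
  pr <- project_trajectory(pt$trajectory, pca, components = 1:2)
  expect_equal(stats::var(pr$pc1), pca$values[1], tolerance = 0.05 * pca$values[1])
  expect_equal(stats::var(pr$pc2), pca$values[2], tolerance = 0.05 * pca$values[2])
  # a frame placed at mean + 3 * PC1 projects to exactly 3
  n <- nrow(pca$mean_coords)
  fr <- pca$mean_coords + unflatten_mat(3 * pca$vectors[, 1])
  tr1 <- cd_trajectory(pt$trajectory$template, list(fr, pca$mean_coords))
  pr1 <- project_trajectory(tr1, pca, components = 1)
  expect_equal(pr1$pc1, c(3, 0), tolerance = 1e-6)
})

test_that("PC-onto-mode overlaps obey Parseval within a complete basis", {
  two <- fixture_two_domain()
  md <- anm_modes(two$structure, n_modes = 20)
  # a PC model whose PC1 is exactly NM2
  fake <- structure(list(values = c(4, 1), vectors = md$vectors[, c(2, 5)],
                         variance_fraction = c(0.8, 0.2), total_variance = 5,
                         mean_coords = md$reference, sel = seq_len(nrow(md$reference)),
                         reference = md$reference, n_frames_used = 100),
                    class = "cd_pca")
  tab <- pc_onto_modes(fake, md, components = 1, mode_indices = 1:3)
  expect_equal(tab$overlap[tab$mode == 2], 1.0, tolerance = 1e-10)
  expect_equal(tab$overlap[tab$mode == 1], 0.0, tolerance = 1e-10)
  # random vector in the span of all 20 modes: squared overlaps sum to 1
  set.seed(10)
  fake$vectors[, 1] <- as.vector(md$vectors %*% rnorm(20)) |> (\(v) v / sqrt(sum(v^2)))()
  tab_all <- pc_onto_modes(fake, md, components = 1, mode_indices = 1:20)
  expect_equal(sum(tab_all$overlap^2), 1.0, tolerance = 1e-8)
})

test_that("cosine content matches its defining cases and an independent quadrature", {
  t <- seq(0, 1, length.out = 1000)
  expect_equal(cosine_content(cos(pi * t)), 1.0, tolerance = 1e-3)
  expect_lt(cosine_content(cos(2 * pi * t), order = 1), 1e-3)
  expect_equal(cosine_content(cos(2 * pi * t), order = 2), 1.0, tolerance = 1e-3)
  # invariance to scaling and sign
  set.seed(12)
  p <- cumsum(rnorm(500))
  expect_equal(cosine_content(p), cosine_content(-3.7 * p), tolerance = 1e-12)
  # independent quadrature oracle on white noise across seeds
  oracle_cc <- function(p) {
    n <- length(p); p <- p - mean(p)
    tt <- (seq_len(n) - 1); T <- n - 1
    f <- cos(pi * tt / T) * p
    int1 <- sum((f[-1] + f[-n]) / 2)
    int2 <- sum((p[-1]^2 + p[-n]^2) / 2)
    (2 / T) * int1^2 / int2
  }
  for (s in 1:50) {
    set.seed(s)
    p <- rnorm(1000)
    expect_equal(cosine_content(p), oracle_cc(p), tolerance = 1e-10)
  }
  expect_error(cosine_content(rep(1, 10)), class = "confdyn_zero_variance")
})

test_that("covariance overlap matches the closed form and the brute-force oracle", {
  two <- fixture_two_domain()
  md <- anm_modes(two$structure, n_modes = 6)
  a <- list(values = c(3, 2, 1), vectors = md$vectors[, 1:3])
  expect_equal(covariance_overlap(a, a), 1.0, tolerance = 1e-12)
  # same eigenvalues, orthogonal eigenvector sets: cross terms vanish
  b <- list(values = c(3, 2, 1), vectors = md$vectors[, 4:6])
  closed <- 1 - sqrt((2 * 6 - 0) / (2 * 6))
  expect_equal(covariance_overlap(a, b), closed, tolerance = 1e-12)
  # random pairs against the literal double loop
  set.seed(14)
  for (rep in 1:5) {
    la <- sort(runif(4, 0.1, 5), decreasing = TRUE)
    lb <- sort(runif(4, 0.1, 5), decreasing = TRUE)
    qa <- qr.Q(qr(matrix(rnorm(36), 9, 4)))
    qb <- qr.Q(qr(matrix(rnorm(36), 9, 4)))
    expect_equal(
      covariance_overlap(list(values = la, vectors = qa),
                         list(values = lb, vectors = qb)),
      oracle_covariance_overlap(la, qa, lb, qb), tolerance = 1e-12)
  }
})

test_that("block covariance overlap behaves on null and correlated data", {
  two <- make_two_domain_structure(10, 4, seed = 61)
  basis <- orthonormal_displacement_basis(two$structure, 3, seed = 62)
  # i.i.d. frames: normalised ratio ~ 1 for every block length
  iid <- make_planted_trajectory(two$structure, basis, c(4, 2, 1), 600, seed = 63)
  bc <- bcom_convergence(iid$trajectory, block_lengths = c(30, 60, 120, 300),
                         n_boot = 15, n_components = 10, seed = 64)
  expect_true(all(abs(bc$curve$normalized - 1) <
                    2.5 * bc$curve$boot_sd / bc$curve$boot_overlap + 0.05))
  expect_true(all(bc$curve$normalized > 0 & bc$curve$normalized <= 1.5))
  # single block of the full length overlaps the full model exactly
  full <- fit_pca(iid$trajectory, n_components = 10)
  expect_equal(covariance_overlap(full, full), 1.0)
  # slow two-state switching: convergence time grows with the switching time
  times <- sapply(c(0.04, 0.01), function(rate) {
    ts <- make_two_state_trajectory(two$structure, basis[, 1], separation = 5,
                                    switch_prob = rate, n_frames = 1200,
                                    jitter_sd = 0.4, seed = 65)
    bc2 <- bcom_convergence(ts$trajectory, block_lengths = c(30, 60, 120, 240, 600),
                            n_boot = 12, n_components = 10, seed = 66)
    # slower switching -> lower early-block normalised overlap
    mean(bc2$curve$normalized[1:2])
  })
  expect_gt(times[1], times[2])
})
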