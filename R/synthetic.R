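# Synthetic-data generators with known ground truth for every analysis stage.
# Each generator is deterministic under a fixed seed and returns its planted
# parameters alongside the data; no analysis function reads the ground truth.

# Rejection-sample n points with minimum separation inside a sphere,
# also avoiding a set of pre-existing points.
sample_compact_cluster <- function(n, center, radius, avoid = matrix(0, 0, 3),
                                   min_sep = 3.5) {
  pts <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(pts) < n) {
    tries <- tries + 1
    if (tries > 20000) { radius <- radius * 1.1; tries <- 0 }
    u <- runif(3, -1, 1)
    if (sum(u^2) > 1) next
    p <- center + u * radius
    all_pts <- rbind(avoid, pts)
    if (nrow(all_pts) == 0 ||
        min(sqrt(rowSums(sweep(all_pts, 2, p)^2))) >= min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

#' Two-domain bead structure with a flexible linker
#'
#' Two compact Calpha bead clusters joined by an extended linker, emulating
#' the two-lobed architecture whose lowest elastic-network modes are
#' inter-domain twisting and bending. Connected at the default 15 Angstrom
#' ANM cutoff.
#'
#' @param n_per_domain Beads per domain (>= 10).
#' @param linker_length Beads in the linker.
#' @param seed RNG seed.
#' @param domain_radius Cluster radius in Angstrom (default scales with n).
#' @return A list with `structure` (`cd_structure` of CA beads), `domains`
#'   (`cd_domains`: domain1, linker, domain2) and `seed`.
#' @export
#' @examples
#' two <- make_two_domain_structure(15, 5, seed = 1)
#' two$structure
make_two_domain_structure <- function(n_per_domain = 30, linker_length = 8,
                                      seed = 1, domain_radius = NULL) {
  if (n_per_domain < 10) stop_confdyn("need >= 10 beads per domain", "bad_input")
  radius <- domain_radius %||% (2.6 * n_per_domain^(1 / 3) + 3)
  with_local_seed(seed, {
    # closed-fold geometry: domain surfaces nearly in contact (a few
    # cross-domain springs at the 15 Angstrom cutoff provide the interdomain
    # interface stiffness) and the linker arcs over the cleft, so the six
    # rigid-body modes are cleanly separated from the softest internal
    # (inter-domain twist/bend) modes
    sep <- 2 * radius + 4
    d1 <- sample_compact_cluster(n_per_domain, c(0, 0, 0), radius)
    d2 <- sample_compact_cluster(n_per_domain, c(sep, 0, 0), radius, avoid = d1)
    rl <- sep / 2 + 3
    phi <- seq(pi, 0, length.out = linker_length + 2)[2:(linker_length + 1)]
    linker <- cbind(sep / 2 + rl * cos(phi),
                    rnorm(linker_length, 0, 0.5),
                    rl * sin(phi) + rnorm(linker_length, 0, 0.5))
    xyz <- rbind(d1, linker, d2)
    n <- nrow(xyz)
    st <- cd_structure(tibble(
      serial = seq_len(n), name = "CA", resname = "ALA", chain = "A",
      resno = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = "C"), title = "synthetic two-domain bead model")
    doms <- domain_definition(
      domain1 = 1:n_per_domain,
      linker = (n_per_domain + 1):(n_per_domain + linker_length),
      domain2 = (n_per_domain + linker_length + 1):n)
    list(structure = st, domains = doms, seed = seed)
  })
}

#' Orthonormal displacement basis free of rigid-body motion
#'
#' Random 3n vectors with the 6 rigid-body components of the reference
#' projected out, then orthonormalised. Useful for planting trajectory
#' covariance that survives superposition.
#'
#' @param reference Structure or coordinate matrix.
#' @param k Number of basis vectors.
#' @param seed RNG seed.
#' @return A 3n x k matrix with orthonormal columns.
#' @export
orthonormal_displacement_basis <- function(reference, k, seed = 1) {
  xyz <- coords(reference)
  with_local_seed(seed, {
    raw <- matrix(rnorm(3 * nrow(xyz) * (k + 6)), ncol = k + 6)
    b <- project_out_rigid(raw, xyz)
    b[, seq_len(k), drop = FALSE]
  })
}

#' Trajectory with planted covariance structure
#'
#' Frames are `reference + sum_i a_i(t) v_i` with independent Gaussian
#' amplitudes of the requested variances, plus optional rigid-body jitter
#' (removed again by superposition during analysis).
#'
#' @param reference Structure or coordinate matrix.
#' @param basis 3n x k matrix with orthonormal columns (checked).
#' @param variances Length-k amplitude variances (Angstrom^2).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param jitter_rotation Rigid rotation jitter, degrees (sd, default 0).
#' @param jitter_translation Rigid translation jitter, Angstrom (sd, default 0).
#' @return A list with `trajectory`, `amplitudes` (n_frames x k ground truth)
#'   and `basis`.
#' @export
make_planted_trajectory <- function(reference, basis, variances, n_frames,
                                    seed = 1, jitter_rotation = 0,
                                    jitter_translation = 0) {
  xyz <- if (inherits(reference, "cd_structure")) {
    idx <- if (any(reference$atoms$name == "CA")) select_atoms(reference, name = "calpha")
           else seq_len(nrow(reference$atoms))
    coords(reference)[idx, , drop = FALSE]
  } else coords(reference)
  k <- ncol(basis)
  if (length(variances) != k) stop_confdyn("one variance per basis vector", "bad_input")
  if (any(variances < 0)) stop_confdyn("variances must be >= 0", "bad_input")
  gram <- crossprod(basis)
  if (max(abs(gram - diag(k))) > 1e-8)
    stop_confdyn("basis is not orthonormal", "bad_input")
  with_local_seed(seed, {
    a <- matrix(rnorm(n_frames * k), n_frames, k) %*% diag(sqrt(variances), k)
    frames <- array(0, dim = c(nrow(xyz), 3, n_frames))
    for (t in seq_len(n_frames)) {
      fr <- xyz + unflatten_coords(as.vector(basis %*% a[t, ]))
      if (jitter_rotation > 0 || jitter_translation > 0) {
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ang <- rnorm(1, 0, jitter_rotation) * pi / 180
        kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
        rot <- diag(3) + sin(ang) * kx + (1 - cos(ang)) * kx %*% kx
        ctr <- colMeans(fr)
        fr <- sweep(fr, 2, ctr) %*% t(rot) +
          matrix(ctr + rnorm(3, 0, jitter_translation), nrow(fr), 3, byrow = TRUE)
      }
      frames[, , t] <- fr
    }
    n <- nrow(xyz)
    template <- cd_structure(tibble(
      serial = seq_len(n), name = "CA", resname = "ALA", chain = "A",
      resno = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = "C"), title = "synthetic planted-covariance trajectory")
    list(trajectory = cd_trajectory(template, frames), amplitudes = a,
         basis = basis)
  })
}

#' Two-state (telegraph) trajectory with known switching
#'
#' A telegraph process hops between two centres at `+/- separation / 2` along
#' a displacement direction, with isotropic Gaussian jitter; the true state
#' labels are returned.
#'
#' @param reference Structure or coordinate matrix.
#' @param direction 3n displacement vector (normalised internally).
#' @param separation Center-to-center distance along the direction
#'   (3n-norm units; > 0).
#' @param switch_prob Per-frame switching probability in (0, 1).
#' @param n_frames Number of frames.
#' @param jitter_sd Per-coordinate Gaussian jitter sd (Angstrom, default 0.5).
#' @param seed RNG seed.
#' @return A list with `trajectory`, `labels` (1/2) and `direction` (unit).
#' @export
make_two_state_trajectory <- function(reference, direction, separation,
                                      switch_prob, n_frames, jitter_sd = 0.5,
                                      seed = 1) {
  if (separation <= 0) stop_confdyn("separation must be > 0", "bad_input")
  if (switch_prob <= 0 || switch_prob >= 1)
    stop_confdyn("switch_prob must be in (0, 1)", "bad_input")
  xyz <- coords(reference)
  dirv <- direction / sqrt(sum(direction^2))
  with_local_seed(seed, {
    state <- integer(n_frames)
    state[1] <- 1
    flips <- runif(n_frames) < switch_prob
    for (t in 2:n_frames) state[t] <- if (flips[t]) 3 - state[t - 1] else state[t - 1]
    frames <- array(0, dim = c(nrow(xyz), 3, n_frames))
    for (t in seq_len(n_frames)) {
      ctr <- (if (state[t] == 1) -1 else 1) * separation / 2
      frames[, , t] <- xyz + unflatten_coords(dirv * ctr) +
        matrix(rnorm(3 * nrow(xyz), 0, jitter_sd), ncol = 3)
    }
    n <- nrow(xyz)
    template <- cd_structure(tibble(
      serial = seq_len(n), name = "CA", resname = "ALA", chain = "A",
      resno = seq_len(n), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = "C"), title = "synthetic two-state trajectory")
    list(trajectory = cd_trajectory(template, frames), labels = state,
         direction = dirv)
  })
}

#' Replica energy table with known lambda-dependent moments
#'
#' Per state, i.i.d. bivariate Gaussian (E1, E2) draws with the requested
#' moments; the exact moment functions are returned as ground truth.
#'
#' @param lambdas Scaling factors in (0, 1].
#' @param mean_fn Function `lambda -> c(mean_E1, mean_E2)` (kJ/mol).
#' @param cov_fn Function `lambda -> 2 x 2 covariance` (positive
#'   semidefinite).
#' @param n_frames Frames per state.
#' @param temperature Temperature in Kelvin.
#' @param seed RNG seed.
#' @return A list with `table` (`cd_retable`), `mean_fn`, `cov_fn`.
#' @export
make_replica_energies <- function(lambdas, mean_fn, cov_fn, n_frames = 1000,
                                  temperature = 300, seed = 1) {
  with_local_seed(seed, {
    rows <- purrr::map(lambdas, function(l) {
      mu <- mean_fn(l); sg <- cov_fn(l)
      ev <- eigen(sg, symmetric = TRUE)
      if (any(ev$values < -1e-8)) stop_confdyn("covariance not PSD", "bad_input")
      rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
      z <- matrix(rnorm(2 * n_frames), n_frames, 2) %*% rt
      tibble(lambda = l, e1 = mu[1] + z[, 1], e2 = mu[2] + z[, 2])
    })
    list(table = replica_energy_table(bind_rows(rows), temperature = temperature),
         mean_fn = mean_fn, cov_fn = cov_fn)
  })
}

# Built-in 1D/2D potentials (kJ/mol) for the biased sampler.
synthetic_potential <- function(density, params, temperature) {
  kt <- kT(temperature)
  switch(density,
    gaussian = {
      mu <- params$mean %||% 0; sdv <- params$sd %||% 1
      list(d = 1, U = function(x) kt * (x - mu)^2 / (2 * sdv^2))
    },
    double_well = {
      a <- params$well %||% 1; h <- params$barrier %||% 3 * kt
      list(d = 1, U = function(x) h * ((x^2 - a^2)^2) / a^4)
    },
    double_well_2d = {
      a <- params$well %||% 1; h <- params$barrier %||% 3 * kt
      ky <- params$k_y %||% kt
      list(d = 2, U = function(x) h * ((x[1]^2 - a^2)^2) / a^4 + ky * x[2]^2 / 2)
    },
    stop_confdyn(paste("unknown density:", density), "bad_input"))
}

#' Metropolis samples from a known density under a known bias
#'
#' Runs a Metropolis chain on the biased Hamiltonian `U(x) + V(x)` — i.e.
#' targeting `p(x) * exp(-V(x)/kT)` with `p` a named analytic density and `V`
#' the supplied bias potential — records the per-sample bias, and returns the
#' true normalised unbiased density on an analysis grid. [opes_weights()]
#' (`w` proportional to `exp(+V/kT)`) undoes exactly this bias, making the
#' pair an oracle bed for reweighting.
#'
#' @param density `"gaussian"`, `"double_well"` or `"double_well_2d"`.
#' @param params Named list of density parameters (`mean`, `sd`, `well`,
#'   `barrier`, `k_y`).
#' @param bias_fn Function of the CV vector returning the bias potential V
#'   (kJ/mol) added to the Hamiltonian during sampling; default zero bias.
#' @param n Number of retained samples.
#' @param grid Break-vector list for the true-density report (default spans
#'   the support).
#' @param temperature Temperature in Kelvin.
#' @param step_size Proposal sd (default 0.5).
#' @param burn_in Discarded initial steps (default 1000).
#' @param thin Keep every `thin`-th step (default 1).
#' @param seed RNG seed.
#' @return A list with `samples` (tibble: cv1 [, cv2], bias), `true_density`
#'   (tibble on the grid), `acceptance_rate`, `grid`.
#' @export
make_biased_samples <- function(density = "double_well", params = list(),
                                bias_fn = NULL, n = 10000, grid = NULL,
                                temperature = 300, step_size = 0.5,
                                burn_in = 1000, thin = 1, seed = 1) {
  pot <- synthetic_potential(density, params, temperature)
  kt <- kT(temperature)
  bias_fn <- bias_fn %||% function(x) 0
  d <- pot$d
  if (is.null(grid)) {
    span <- if (density == "gaussian") {
      mu <- params$mean %||% 0; sdv <- params$sd %||% 1
      c(mu - 5 * sdv, mu + 5 * sdv)
    } else {
      a <- params$well %||% 1
      c(-3 * a, 3 * a)
    }
    grid <- fes_grid(rep(span[1], d), rep(span[2], d), rep(60, d))
  }
  with_local_seed(seed, {
    x <- rep(0.01, d)
    log_target <- function(x) (-pot$U(x) - bias_fn(x)) / kt
    lt <- log_target(x)
    n_steps <- burn_in + n * thin
    keep <- matrix(0, n, d)
    bias_kept <- numeric(n)
    n_acc <- 0; ki <- 0
    for (s in seq_len(n_steps)) {
      prop <- x + rnorm(d, 0, step_size)
      ltp <- log_target(prop)
      if (log(runif(1)) < ltp - lt) { x <- prop; lt <- ltp; n_acc <- n_acc + 1 }
      if (s > burn_in && (s - burn_in) %% thin == 0) {
        ki <- ki + 1
        keep[ki, ] <- x
        bias_kept[ki] <- bias_fn(x)
      }
    }
    acc_rate <- n_acc / n_steps
    if (acc_rate == 0)
      stop_confdyn("Metropolis acceptance is zero; step size pathological", "sampler")
    samples <- as_tibble(as.data.frame(keep))
    names(samples) <- paste0("cv", seq_len(d))
    samples$bias <- bias_kept
    # true unbiased density, normalised on the grid and averaged over each
    # bin (the quantity a histogram estimator converges to)
    centers <- purrr::map(grid, function(b) (b[-1] + b[-length(b)]) / 2)
    gt <- if (d == 1) tibble(cv1 = centers[[1]])
          else as_tibble(expand.grid(cv1 = centers[[1]], cv2 = centers[[2]]))
    nsub <- 9
    sub_offsets <- (seq_len(nsub) - 0.5) / nsub
    bin_mean_density <- function(lo_vec, hi_vec) {
      pts <- expand.grid(lapply(seq_len(d), function(k)
        lo_vec[k] + (hi_vec[k] - lo_vec[k]) * sub_offsets))
      mean(exp(-apply(as.matrix(pts), 1, function(r) pot$U(as.numeric(r))) / kt))
    }
    lows <- purrr::map(grid, function(b) b[-length(b)])
    highs <- purrr::map(grid, function(b) b[-1])
    bins <- if (d == 1) cbind(lo1 = lows[[1]], hi1 = highs[[1]])
            else cbind(expand.grid(lo1 = lows[[1]], lo2 = lows[[2]]),
                       expand.grid(hi1 = highs[[1]], hi2 = highs[[2]]))
    dens <- vapply(seq_len(nrow(gt)), function(i) {
      lo <- as.numeric(bins[i, seq_len(d)])
      hi <- as.numeric(bins[i, d + seq_len(d)])
      bin_mean_density(lo, hi)
    }, 0)
    widths <- prod(purrr::map_dbl(grid, function(b) mean(diff(b))))
    gt$density <- dens / (sum(dens) * widths)
    list(samples = samples, true_density = gt, acceptance_rate = acc_rate,
         grid = grid)
  })
}

#' Ring and membrane coordinate fixtures with planted geometry
#'
#' Builds a donor-like anisotropic point cloud whose inertia axes are the
#' coordinate axes (ascending moment = x, y, z), a planar hexagonal ring
#' whose normal has planted polar angles (gamma from the largest-moment axis,
#' theta in the plane of the other two), a phosphate point cloud with an
#' exact mean plane at `plane_offset`, and probe points at declared signed
#' distances. A random rigid transform applied jointly to the cloud and the
#' ring exercises the alignment step; the transform is returned.
#'
#' @param gamma,theta Planted ring-normal angles in degrees (`gamma` in
#'   (0, 90) so the first-frame sign convention recovers it exactly).
#' @param plane_offset Membrane plane height in Angstrom (default 12).
#' @param probe_distances Signed distances of probe points from the plane
#'   (default 40).
#' @param rigid_transform Apply a random rotation+translation to the frame
#'   copy (default TRUE).
#' @param seed RNG seed.
#' @return A list with `reference` (donor cloud, n x 3), `ring_reference`
#'   (ring in the reference frame), `frame` (transformed cloud),
#'   `ring_frame`, `ring_idx`, `domain_sel`, `phosphates`, `probes`,
#'   `truth` (gamma, theta, plane_offset, probe_distances).
#' @export
make_ring_and_membrane_fixtures <- function(gamma, theta, plane_offset = 12,
                                            probe_distances = 40,
                                            rigid_transform = TRUE, seed = 1) {
  if (gamma <= 0 || gamma >= 90)
    stop_confdyn("plant gamma in (0, 90) degrees", "bad_input")
  # anisotropic grid: spreads x > y > z so moments ascend as x, y, z
  gx <- seq(-12, 12, by = 4); gy <- seq(-8, 8, by = 4); gz <- seq(-4, 4, by = 4)
  cloud <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dimnames(cloud) <- NULL
  axes <- inertia_axes(cloud)
  g <- gamma * pi / 180; th <- theta * pi / 180
  nrm <- sin(g) * cos(th) * axes[, 1] + sin(g) * sin(th) * axes[, 2] +
    cos(g) * axes[, 3]
  # hexagon of radius 1.4 perpendicular to the planted normal
  u <- cross3(nrm, if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
  u <- u / sqrt(sum(u^2))
  v <- cross3(nrm, u)
  ctr <- c(20, 0, 5)
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- t(vapply(ang, function(a) ctr + 1.4 * (cos(a) * u + sin(a) * v),
                   numeric(3)))
  with_local_seed(seed, {
    frame_cloud <- cloud; frame_ring <- ring; rot <- diag(3); trans <- c(0, 0, 0)
    if (rigid_transform) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      a0 <- runif(1, 0.3, 2.5)
      kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
      rot <- diag(3) + sin(a0) * kx + (1 - cos(a0)) * kx %*% kx
      trans <- rnorm(3, 0, 10)
      frame_cloud <- cloud %*% t(rot) + matrix(trans, nrow(cloud), 3, byrow = TRUE)
      frame_ring <- ring %*% t(rot) + matrix(trans, nrow(ring), 3, byrow = TRUE)
    }
    np <- 200
    ph <- cbind(runif(np, -40, 40), runif(np, -40, 40), rnorm(np, 0, 1.5))
    ph[, 3] <- ph[, 3] - mean(ph[, 3]) + plane_offset   # exact mean plane
    probes <- cbind(0, 0, plane_offset + probe_distances)
    list(reference = cloud, ring_reference = ring, frame = frame_cloud,
         ring_frame = frame_ring,
         reference_all = rbind(cloud, ring), frame_all = rbind(frame_cloud, frame_ring),
         ring_idx = nrow(cloud) + seq_len(6), domain_sel = seq_len(nrow(cloud)),
         phosphates = ph, probes = probes,
         rotation = rot, translation = trans,
         truth = list(gamma = gamma, theta = theta,
                      plane_offset = plane_offset,
                      probe_distances = probe_distances))
  })
}
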