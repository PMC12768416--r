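test_that("state-model fitting recovers constant and interpolated moments", {
  tab <- replica_energy_table(tibble::tibble(
    lambda = rep(c(0.5, 1.0), each = 3),
    e1 = c(-100, -100, -100, -200, -200, -200),
    e2 = c(50, 50, 50, 80, 80, 80)))
  sm <- fit_state_model(tab)
  expect_equal(sm$means[, sm$lambda == 0.5], c(-100, 50))
  expect_equal(max(abs(sm$covs)), 0)
  mid <- confdyn:::state_moments(sm, 0.75)
  expect_equal(mid$mean, c(-150, 65))
  expect_warning(confdyn:::state_moments(sm, 0.2), "clamped")
  expect_error(replica_energy_table(tibble::tibble(lambda = 1.5, e1 = 1, e2 = 1)),
               class = "confdyn_bad_input")
})

test_that("state-model estimates are consistent on Gaussian synthetic tables", {
  mean_fn <- function(l) c(-500 + 100 * l, 40 + 20 * l)
  cov_fn <- function(l) matrix(c(400, 60, 60, 100), 2) * l
  mt <- make_replica_energies(c(0.4, 0.7, 1.0), mean_fn, cov_fn,
                              n_frames = 1e5, seed = 31)
  sm <- fit_state_model(mt$table)
  for (k in seq_along(sm$lambda)) {
    l <- sm$lambda[k]
    se <- sqrt(diag(cov_fn(l)) / 1e5)
    expect_true(all(abs(sm$means[, k] - mean_fn(l)) < 3 * se + 1e-9))
    expect_lt(max(abs(sm$covs[, , k] / cov_fn(l) - 1)), 0.05)
  }
})

test_that("closed-form acceptance matches the Monte-Carlo oracle", {
  mt <- make_replica_energies(seq(0.3, 1, by = 0.1), bath_mean_fn(150),
                              bath_cov_fn(150), n_frames = 4000, seed = 32)
  sm <- fit_state_model(mt$table)
  expect_equal(predict_acceptance(sm, 0.8, 0.8), 1.0)
  for (pair in list(c(1.0, 0.95), c(1.0, 0.85), c(0.6, 0.5), c(0.4, 0.3))) {
    p_closed <- predict_acceptance(sm, pair[1], pair[2])
    p_mc <- oracle_mc_acceptance(sm, pair[1], pair[2], n_draw = 2e5, seed = 33)
    expect_lt(abs(p_closed - p_mc), 0.01)
    # symmetry
    expect_equal(p_closed, predict_acceptance(sm, pair[2], pair[1]),
                 tolerance = 1e-12)
  }
  # degenerate model: no fluctuations and identical means -> certain exchange
  flat <- fit_state_model(replica_energy_table(tibble::tibble(
    lambda = rep(c(0.5, 1), each = 2), e1 = -10, e2 = 5)))
  expect_equal(predict_acceptance(flat, 1.0, 0.5), 1.0)
})

test_that("acceptance grows to 1 as the lambda gap closes", {
  mt <- make_replica_energies(seq(0.3, 1, by = 0.1), bath_mean_fn(300),
                              bath_cov_fn(300), n_frames = 4000, seed = 34)
  sm <- fit_state_model(mt$table)
  gaps <- c(0.3, 0.2, 0.1, 0.05, 0.02, 0.005, 0.0005)
  accs <- sapply(gaps, function(g) predict_acceptance(sm, 1.0, 1.0 - g))
  expect_true(all(diff(accs) > 0))
  expect_gt(accs[length(accs)], 0.99)
})

test_that("ladder optimisation hits the target and matches a grid search", {
  # exact gap-only model: E1 mean linear in lambda (so the exchange
  # exponent's mean is proportional to gap^2), constant E1 variance, inert E2
  sm <- structure(list(
    lambda = c(0.3, 1.0),
    means = cbind(c(-550 * 0.3, 50), c(-550 * 1.0, 50)),
    covs = array(rep(diag(c(1e4, 0)), 2), dim = c(2, 2, 2)),
    temperature = 300), class = "cd_state_model")
  lad <- optimize_ladder(sm, target = 0.35)
  accs <- lad$acceptance_to_next[!is.na(lad$acceptance_to_next)]
  # every pair within tolerance except possibly the final clamped one
  if (length(accs) > 1)
    expect_true(all(abs(accs[-length(accs)] - 0.35) <= 1e-3))
  expect_true(all(diff(lad$lambda) < 0))
  expect_equal(lad$lambda[1], 1.0)
  expect_equal(lad$lambda[nrow(lad)], 0.3)
  # acceptance depends only on the gap -> uniform spacing (within the
  # gap-equivalent of the 1e-3 acceptance tolerance)
  gaps <- -diff(lad$lambda)
  expect_lt(max(abs(gaps[-length(gaps)] - gaps[1])), 2e-3)
  # grid-search oracle for the first step: smallest gap with acc == target
  g_grid <- seq(1e-4, 0.7, by = 1e-4)
  a_grid <- sapply(g_grid, function(g) predict_acceptance(sm, 1.0, 1.0 - g))
  g_star <- g_grid[which.min(abs(a_grid - 0.35))]
  expect_lt(abs(gaps[1] - g_star), 1.5e-3)
  # near-degenerate model: trivially easy exchange -> two-rung ladder
  easy <- fit_state_model(replica_energy_table(tibble::tibble(
    lambda = rep(c(0.3, 1), each = 2), e1 = c(-10, -10 + 1e-8, -10, -10 + 1e-8),
    e2 = 5)))
  lad2 <- optimize_ladder(easy, target = 0.999)
  expect_equal(nrow(lad2), 2)
  expect_equal(lad2$lambda, c(1.0, 0.3))
})

test_that("ladder optimisation is idempotent on its own output", {
  mt <- make_replica_energies(seq(0.3, 1, by = 0.1), bath_mean_fn(200),
                              bath_cov_fn(200), n_frames = 4000, seed = 36)
  sm <- fit_state_model(mt$table)
  lad1 <- optimize_ladder(sm, target = 0.3)
  lad2 <- optimize_ladder(sm, target = 0.3)
  expect_equal(lad1$lambda, lad2$lambda, tolerance = 1e-3)
})

test_that("replica diagnostics recount occupancy, rates and MSD", {
  # no exchanges: identity occupancy, zero MSD
  series <- matrix(rep(1:3, each = 10), 10, 3)
  d <- replica_diagnostics(series)
  expect_equal(unname(d$occupancy), diag(3))
  expect_true(all(d$msd$msd == 0))
  # deterministic full swap every step on 2 states
  swap <- cbind(rep(c(1, 2), 10), rep(c(2, 1), 10))
  log2 <- tibble::tibble(pair = 1, attempted = 19, accepted = 19)
  d2 <- replica_diagnostics(swap, exchange_log = log2)
  expect_equal(d2$rates$rate, 1.0)
  expect_equal(d2$msd$msd[1], 1.0)
  expect_true(all(abs(rowSums(d2$occupancy) - 1) < 1e-12))
  # random-walk ladder process vs naive recount
  set.seed(37)
  n_steps <- 200; n_rep <- 4
  walk <- matrix(0L, n_steps, n_rep)
  walk[1, ] <- 1:4
  for (t in 2:n_steps) {
    walk[t, ] <- walk[t - 1, ]
    i <- sample(3, 1)
    a <- which(walk[t, ] == i); b <- which(walk[t, ] == i + 1)
    if (runif(1) < 0.5) { walk[t, a] <- i + 1L; walk[t, b] <- i }
  }
  d3 <- replica_diagnostics(walk, max_lag = 50)
  occ_naive <- t(sapply(1:n_rep, function(r)
    sapply(1:4, function(s) mean(walk[, r] == s))))
  expect_equal(unname(d3$occupancy), occ_naive, tolerance = 1e-12)
  msd_naive <- sapply(1:50, function(tau)
    mean((walk[(tau + 1):n_steps, ] - walk[1:(n_steps - tau), ])^2))
  expect_equal(d3$msd$msd, msd_naive, tolerance = 1e-12)
})

test_that("replica energy tables round-trip through FIELDS files", {
  mt <- make_replica_energies(c(0.5, 1.0), function(l) c(-l, l),
                              function(l) diag(c(1, 1)), n_frames = 50, seed = 38)
  paths <- c(tempfile(), tempfile())
  for (i in 1:2) {
    sub <- mt$table[mt$table$lambda == c(0.5, 1.0)[i], ]
    write_colvar(tibble::tibble(time = seq_len(nrow(sub)), E1 = sub$e1, E2 = sub$e2),
                 paths[i])
  }
  back <- read_replica_energies(paths, c(0.5, 1.0))
  expect_equal(back$e1, mt$table$e1, tolerance = 1e-10)
})
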