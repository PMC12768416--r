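# Hamiltonian replica exchange with interaction scaling: when Coulomb, van
# der Waals and dihedral terms are scaled by lambda the total potential is
# U(s; x) = E0(x) + s E1(x) + s^2 E2(x), so a single trial ladder determines
# the (E1, E2) statistics of every state and exchange acceptance between
# arbitrary scaling factors can be predicted in closed form.

#' Per-state replica energy table
#'
#' Stores per-frame linear (E1) and quadratic (E2) energy coefficients for a
#' set of scaling factors. E0 cancels in every exchange and is not needed.
#'
#' @param data A data frame with columns `lambda`, `e1`, `e2` (kJ/mol).
#' @param temperature Temperature in Kelvin (default 300).
#' @return A `cd_retable` (tibble subclass with a `temperature` attribute).
#' @export
replica_energy_table <- function(data, temperature = 300) {
  data <- as_tibble(data)
  if (!all(c("lambda", "e1", "e2") %in% names(data)))
    stop_confdyn("need columns lambda, e1, e2", "bad_input")
  lam <- sort(unique(data$lambda))
  if (any(lam <= 0) || any(lam > 1))
    stop_confdyn("scaling factors must lie in (0, 1]", "bad_input")
  counts <- table(data$lambda)
  if (any(counts < 2)) stop_confdyn("every state needs >= 2 frames", "bad_input")
  structure(data, class = c("cd_retable", class(data)), temperature = temperature)
}

#' Read per-state `#! FIELDS time E1 E2` files into a replica energy table
#'
#' @param paths One file per trial state.
#' @param lambdas Scaling factor of each file.
#' @param temperature Temperature in Kelvin.
#' @return A `cd_retable`.
#' @export
read_replica_energies <- function(paths, lambdas, temperature = 300) {
  stopifnot(length(paths) == length(lambdas))
  rows <- purrr::map2(paths, lambdas, function(p, l) {
    d <- read_colvar(p)
    tibble(lambda = l, e1 = d$E1, e2 = d$E2)
  })
  replica_energy_table(bind_rows(rows), temperature = temperature)
}

#' Fit the Gaussian state model of a trial ladder
#'
#' Per trial scaling factor, the sample mean and 2x2 covariance of (E1, E2);
#' between trial values the moments are interpolated linearly in lambda, and
#' queries outside the trial range are clamped with a warning.
#'
#' @param table A `cd_retable`.
#' @return A `cd_state_model` with `lambda`, `means` (2 x K), `covs`
#'   (2 x 2 x K), `temperature`.
#' @export
fit_state_model <- function(table) {
  if (!inherits(table, "cd_retable")) table <- replica_energy_table(table)
  lam <- sort(unique(table$lambda))
  if (length(lam) < 2) stop_confdyn("need >= 2 trial states", "bad_input")
  means <- matrix(0, 2, length(lam))
  covs <- array(0, dim = c(2, 2, length(lam)))
  for (k in seq_along(lam)) {
    sub <- table[table$lambda == lam[k], c("e1", "e2")]
    means[, k] <- colMeans(sub)
    covs[, , k] <- stats::cov(sub)
  }
  structure(list(lambda = lam, means = means, covs = covs,
                 temperature = attr(table, "temperature") %||% 300),
            class = "cd_state_model")
}

# Interpolated (mean, covariance) of (E1, E2) at scaling factor s.
state_moments <- function(model, s) {
  lam <- model$lambda
  if (s < min(lam) || s > max(lam)) {
    rlang::warn(sprintf("scaling factor %.3f outside trial range [%.3f, %.3f]; clamped",
                        s, min(lam), max(lam)))
    s <- max(min(s, max(lam)), min(lam))
  }
  if (s <= lam[1]) return(list(mean = model$means[, 1], cov = model$covs[, , 1]))
  k <- findInterval(s, lam, rightmost.closed = TRUE)
  w <- (s - lam[k]) / (lam[k + 1] - lam[k])
  list(mean = (1 - w) * model$means[, k] + w * model$means[, k + 1],
       cov = (1 - w) * model$covs[, , k] + w * model$covs[, , k + 1])
}

#' Predicted exchange acceptance between two scaling factors
#'
#' The Metropolis exponent for swapping configurations between states `s_a`
#' and `s_b` is
#' `Delta = beta (s_a - s_b) ((E1_b - E1_a) + (s_a + s_b)(E2_b - E2_a))`
#' (E0 cancels identically). With (E1, E2) Gaussian and the two replicas
#' independent, Delta is Gaussian with moments from the state model, and the
#' expected acceptance `E[min(1, exp(-Delta))]` has the closed form
#' `Phi(-mu/sigma) + exp(sigma^2/2 - mu) Phi((mu - sigma^2)/sigma)`; for
#' `sigma = 0` it degenerates to `min(1, exp(-mu))`.
#'
#' @param model A `cd_state_model`.
#' @param s_a,s_b Scaling factors (clamped to the trial range).
#' @param temperature Temperature in Kelvin (default: the model's).
#' @return Acceptance probability in `[0, 1]`.
#' @export
predict_acceptance <- function(model, s_a, s_b, temperature = NULL) {
  temperature <- temperature %||% model$temperature
  if (s_a == s_b) return(1.0)
  beta <- 1 / kT(temperature)
  ma <- state_moments(model, s_a); mb <- state_moments(model, s_b)
  cvec <- beta * (s_a - s_b) * c(1, s_a + s_b)
  mu <- sum(cvec * (mb$mean - ma$mean))
  sig2 <- as.numeric(t(cvec) %*% (ma$cov + mb$cov) %*% cvec)
  if (!is.finite(mu) || !is.finite(sig2))
    stop_confdyn("non-finite state moments", "bad_input")
  if (sig2 <= 0) return(min(1, exp(-mu)))
  sig <- sqrt(sig2)
  p <- pnorm(-mu / sig) +
    exp(sig2 / 2 - mu + pnorm((mu - sig2) / sig, log.p = TRUE))
  max(0, min(1, p))
}

#' Optimise a lambda ladder for uniform neighbour acceptance
#'
#' Starting from `lambda_max`, each next rung is found by bisection so the
#' predicted acceptance with the current rung equals `target` within `tol`;
#' when even `lambda_min` exceeds the target the ladder is closed with
#' `lambda_min` as final rung.
#'
#' @param model A `cd_state_model`.
#' @param lambda_min,lambda_max Ladder range (defaults 0.3 and 1.0).
#' @param target Target neighbour acceptance in (0, 1) (default 0.30).
#' @param temperature Temperature in Kelvin (default: the model's).
#' @param tol Acceptance tolerance for the bisection (default 1e-3).
#' @return A `cd_ladder`: tibble with `rung`, `lambda`,
#'   `acceptance_to_next` (NA for the last rung), plus attributes `target`
#'   and `temperature`.
#' @export
optimize_ladder <- function(model, lambda_min = 0.3, lambda_max = 1.0,
                            target = 0.30, temperature = NULL, tol = 1e-3) {
  if (!(lambda_min > 0 && lambda_min < lambda_max && lambda_max <= 1))
    stop_confdyn("need 0 < lambda_min < lambda_max <= 1", "bad_input")
  if (target <= 0 || target >= 1) stop_confdyn("target must be in (0, 1)", "bad_input")
  temperature <- temperature %||% model$temperature
  acc <- function(a, b) suppressWarnings(predict_acceptance(model, a, b, temperature))
  rungs <- lambda_max
  repeat {
    cur <- rungs[length(rungs)]
    if (acc(cur, lambda_min) >= target - tol) { rungs <- c(rungs, lambda_min); break }
    if (acc(cur, cur - min(1e-9, (cur - lambda_min) / 2)) < target) {
      stop_confdyn(sprintf(
        "target %.3f unreachable below lambda = %.4f (max achievable %.4f)",
        target, cur, acc(cur, cur - 1e-9)), "unreachable_target")
    }
    lo <- lambda_min; hi <- cur
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      a <- acc(cur, mid)
      if (abs(a - target) <= tol) break
      if (a > target) hi <- mid else lo <- mid
    }
    rungs <- c(rungs, mid)
    if (length(rungs) > 1000)
      stop_confdyn("ladder exceeds 1000 rungs; model too stiff", "unreachable_target")
  }
  accs <- c(vapply(seq_len(length(rungs) - 1),
                   function(i) acc(rungs[i], rungs[i + 1]), 0), NA_real_)
  out <- tibble(rung = seq_along(rungs), lambda = rungs, acceptance_to_next = accs)
  structure(out, class = c("cd_ladder", class(out)),
            target = target, temperature = temperature)
}

#' Replica-exchange diagnostics
#'
#' Occupancy probability matrix (fraction of time each replica spends in each
#' ladder state; rows sum to 1), per-neighbour exchange rates from an
#' attempted/accepted log, and the replica-index mean-square displacement
#' versus lag.
#'
#' @param state_series Integer matrix, `n_steps x n_replicas`: ladder position
#'   of each replica over time.
#' @param exchange_log Optional tibble with `pair` (lower neighbour index),
#'   `attempted`, `accepted`.
#' @param max_lag Largest lag for the MSD (default `n_steps - 1`, capped at
#'   200).
#' @return A `cd_replica_diag`: `occupancy` (n_replicas x n_states),
#'   `rates` (tibble or NULL), `msd` (tibble: lag, msd).
#' @export
replica_diagnostics <- function(state_series, exchange_log = NULL, max_lag = NULL) {
  m <- as.matrix(state_series)
  n_steps <- nrow(m); n_rep <- ncol(m)
  states <- sort(unique(as.vector(m)))
  occ <- t(apply(m, 2, function(col) {
    tab <- table(factor(col, levels = states))
    as.numeric(tab) / n_steps
  }))
  dimnames(occ) <- list(replica = seq_len(n_rep), state = states)
  rates <- NULL
  if (!is.null(exchange_log)) {
    el <- as_tibble(exchange_log)
    if (any(el$attempted < el$accepted))
      stop_confdyn("accepted exceeds attempted", "bad_input")
    rates <- mutate(el, rate = ifelse(.data$attempted > 0,
                                      .data$accepted / .data$attempted, NA_real_))
  }
  max_lag <- max_lag %||% min(n_steps - 1, 200)
  msd <- tibble(lag = seq_len(max_lag),
                msd = vapply(seq_len(max_lag), function(tau) {
                  d <- m[(tau + 1):n_steps, , drop = FALSE] -
                       m[1:(n_steps - tau), , drop = FALSE]
                  mean(d^2)
                }, 0))
  structure(list(occupancy = occ, rates = rates, msd = msd),
            class = "cd_replica_diag")
}

#' @export
print.cd_replica_diag <- function(x, ...) {
  cat("<cd_replica_diag>", nrow(x$occupancy), "replicas x",
      ncol(x$occupancy), "states\n")
  invisible(x)
}

#' Write a ladder as a plain lambda list
#'
#' @param ladder A `cd_ladder`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ladder <- function(ladder, path) {
  writeLines(sprintf("%.6f", ladder$lambda), path)
  invisible(path)
}
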