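# Frame weights from bias potentials and multi-state energies, weighted
# free-energy surfaces, and density convergence curves.

#' Frame weights from a recorded bias potential
#'
#' For an adaptive-bias run whose final bias V was recorded per frame, the
#' unbiased weight of frame t is `w_t` proportional to `exp(V_t / kT)`
#' (consumed-bias semantics: the bias is taken as given). Stabilised by
#' subtracting `max(V)` before exponentiation.
#'
#' @param bias Per-frame bias values (kJ/mol), finite.
#' @param temperature Temperature in Kelvin (default 300).
#' @return Normalised weights summing to 1.
#' @export
opes_weights <- function(bias, temperature = 300) {
  if (length(bias) == 0) stop_confdyn("empty bias series", "empty_input")
  if (!all(is.finite(bias))) stop_confdyn("non-finite bias values", "bad_input")
  w <- exp((bias - max(bias)) / kT(temperature))
  w / sum(w)
}

#' Effective sample size of a weight vector
#'
#' `1 / sum(w^2)` for normalised weights.
#'
#' @param weights Normalised weights.
#' @return Effective sample size.
#' @export
effective_sample_size <- function(weights) 1 / sum((weights / sum(weights))^2)

#' Binless WHAM over pooled multi-state samples
#'
#' Self-consistent solution of
#' `f_i = -ln sum_n exp(-u_i(x_n)) / sum_j N_j exp(f_j - u_j(x_n))`
#' with the gauge `f_1 = 0`, iterated with log-sum-exp stabilisation until
#' `max |delta f| < tol`. The unbiased frame weights are
#' `w_n` proportional to `1 / sum_j N_j exp(f_j - u_j(x_n))`.
#'
#' @param reduced_energies K x N matrix: every pooled frame evaluated in every
#'   state's reduced potential (u = U / kT, dimensionless).
#' @param frames_per_state Length-K sample counts per state (default: N / K
#'   each when N is divisible).
#' @param target The ensemble the weights reweight to: a state index (default
#'   1), or a length-N numeric vector of target reduced energies (e.g. zeros
#'   when the `u` rows are pure bias energies relative to the unbiased
#'   system).
#' @param tol Convergence tolerance on f (default 1e-10).
#' @param max_iter Iteration cap (default 1e5).
#' @param damping Step damping in (0, 1] (default 1, plain fixed point).
#' @return A `cd_wham`: `f` (state free energies, kT units, f[1] = 0),
#'   `weights` (normalised, reweighting the pooled frames to the target
#'   ensemble), `ess`, `iterations`, `converged`.
#' @export
binless_wham <- function(reduced_energies, frames_per_state = NULL,
                         target = 1, tol = 1e-10, max_iter = 1e5, damping = 1) {
  u <- as.matrix(reduced_energies)
  K <- nrow(u); N <- ncol(u)
  if (is.null(frames_per_state)) {
    if (N %% K != 0)
      stop_confdyn("frames_per_state required when N is not divisible by K", "bad_input")
    frames_per_state <- rep(N / K, K)
  }
  if (length(frames_per_state) != K || sum(frames_per_state) != N)
    stop_confdyn("frames_per_state must sum to the pooled frame count", "bad_input")
  u_target <- if (length(target) == 1 && target %in% seq_len(K)) u[target, ]
              else if (length(target) == N) as.numeric(target)
              else stop_confdyn("target must be a state index or length-N vector", "bad_input")
  logN <- log(frames_per_state)
  f <- rep(0, K)
  iter <- 0L; converged <- K == 1
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    log_denom <- col_logsumexp(logN + f - u)
    f_new <- -vapply(seq_len(K), function(i) logsumexp(-u[i, ] - log_denom), 0)
    f_new <- f_new - f_new[1]
    f_upd <- f + damping * (f_new - f)
    delta <- max(abs(f_upd - f))
    f <- f_upd
    if (delta < tol) converged <- TRUE
  }
  if (!converged) {
    overlap <- exp(-abs(outer(f, f, "-")))
    stop_confdyn(paste0(
      "WHAM failed to converge in ", max_iter, " iterations; ",
      "minimum pairwise state overlap proxy ", signif(min(overlap), 3),
      " suggests non-overlapping states"), "no_convergence")
  }
  log_denom <- if (K == 1) logN + f - u[1, ] else col_logsumexp(logN + f - u)
  logw <- as.vector(-u_target - log_denom)
  w <- exp(logw - logsumexp(logw))
  structure(list(f = f, weights = w, ess = effective_sample_size(w),
                 iterations = iter, converged = converged), class = "cd_wham")
}

#' @export
print.cd_wham <- function(x, ...) {
  cat("<cd_wham>", length(x$f), "states, converged in", x$iterations,
      "iterations; ESS", round(x$ess, 1), "\n")
  cat("  f (kT):", paste(signif(x$f, 6), collapse = ", "), "\n")
  invisible(x)
}

# Resolve a grid specification: list of break vectors, or list(min, max, bins).
resolve_grid <- function(grid_spec, d) {
  if (is.list(grid_spec) && all(vapply(grid_spec, is.numeric, TRUE)) &&
      length(grid_spec) == d && all(lengths(grid_spec) > 2)) {
    return(grid_spec)
  }
  stop_confdyn("grid_spec must be a list of break vectors, one per dimension", "bad_input")
}

#' Evenly spaced grid breaks
#'
#' @param min,max Grid range per dimension (recycled).
#' @param bins Bin counts per dimension.
#' @return A list of break vectors usable as `grid_spec`.
#' @export
fes_grid <- function(min, max, bins) {
  n <- max(length(min), length(max), length(bins))
  min <- rep(min, length.out = n); max <- rep(max, length.out = n)
  bins <- rep(bins, length.out = n)
  purrr::map(seq_len(n), function(k) seq(min[k], max[k], length.out = bins[k] + 1))
}

# Weighted histogram over a 1D/2D grid -> tibble of bins with density.
weighted_histogram <- function(values, weights, breaks_list) {
  d <- length(breaks_list)
  values <- as.matrix(values)
  if (ncol(values) != d) stop_confdyn("dimension mismatch with grid", "bad_input")
  inside <- rep(TRUE, nrow(values))
  idx <- matrix(0L, nrow(values), d)
  for (k in seq_len(d)) {
    br <- breaks_list[[k]]
    ik <- findInterval(values[, k], br, rightmost.closed = TRUE)
    inside <- inside & ik >= 1 & ik <= length(br) - 1
    idx[, k] <- ik
  }
  if (!any(inside)) stop_confdyn("all samples fall outside the grid", "empty_input")
  nb <- vapply(breaks_list, function(b) length(b) - 1L, 1L)
  lin <- idx[, 1]
  if (d == 2) lin <- idx[, 1] + (idx[, 2] - 1L) * nb[1]
  mass <- rep(0, prod(nb))
  agg <- rowsum(weights[inside], lin[inside])
  mass[as.integer(rownames(agg))] <- agg
  centers <- purrr::map(breaks_list, function(b) (b[-1] + b[-length(b)]) / 2)
  grid <- if (d == 1) tibble(cv1 = centers[[1]])
          else as_tibble(expand.grid(cv1 = centers[[1]], cv2 = centers[[2]]))
  widths <- purrr::map_dbl(breaks_list, function(b) mean(diff(b)))
  grid$density <- mass / (sum(weights[inside]) * prod(widths))
  grid$mass <- mass / sum(weights[inside])
  grid
}

#' Weighted free-energy surface on a grid
#'
#' Weighted histogram of the samples, then `F = -kT ln(density)`, min-shifted
#' so the lowest populated bin is 0. Empty bins are masked (`populated =
#' FALSE`, `free_energy = NA`), never reported as 0.
#'
#' @param samples A data frame whose first 1-2 columns are collective-variable
#'   values; a `weight` column is used if present, else uniform weights.
#' @param grid_spec A list of break vectors (see [fes_grid()]).
#' @param temperature Temperature in Kelvin (default 300).
#' @return A `cd_fes` tibble with the bin centers, `density`, `free_energy`
#'   (kJ/mol) and `populated`, plus attributes `breaks` and `temperature`.
#' @export
weighted_fes <- function(samples, grid_spec, temperature = 300) {
  samples <- as_tibble(samples)
  w <- if ("weight" %in% names(samples)) samples$weight
       else rep(1 / nrow(samples), nrow(samples))
  if (any(w < 0)) stop_confdyn("negative weights", "bad_input")
  cvs <- samples[, setdiff(names(samples), "weight"), drop = FALSE]
  d <- ncol(cvs)
  if (d < 1 || d > 2) stop_confdyn("1 or 2 collective variables supported", "bad_input")
  breaks_list <- resolve_grid(grid_spec, d)
  h <- weighted_histogram(as.matrix(cvs), w, breaks_list)
  h$populated <- h$density > 0
  fe <- ifelse(h$populated, -kT(temperature) * log(h$density), NA_real_)
  fe <- fe - min(fe, na.rm = TRUE)
  h$free_energy <- fe
  structure(h, class = c("cd_fes", class(h)), breaks = breaks_list,
            temperature = temperature,
            ess = effective_sample_size(w))
}

#' Convergence of a cumulative density estimate
#'
#' At each checkpoint the cumulative weighted density on the grid is compared
#' with a reference density (the first checkpoint's, or the final one's) by
#' root-mean-square deviation over the bins populated in either.
#'
#' @param samples A data frame of CV values (+ optional `weight`), in time
#'   order.
#' @param grid_spec A list of break vectors.
#' @param checkpoints Increasing frame counts (>= 2 checkpoints).
#' @param reference `"initial"` or `"final"`.
#' @return A tibble with `checkpoint`, `n_frames`, `rmsd`.
#' @export
density_rmsd_curve <- function(samples, grid_spec, checkpoints,
                               reference = c("initial", "final")) {
  reference <- match.arg(reference)
  samples <- as_tibble(samples)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (length(checkpoints) < 2) stop_confdyn("need >= 2 checkpoints", "bad_input")
  if (any(checkpoints < 1) || max(checkpoints) > nrow(samples))
    stop_confdyn("checkpoints out of range", "bad_input")
  w <- if ("weight" %in% names(samples)) samples$weight
       else rep(1, nrow(samples))
  cvs <- as.matrix(samples[, setdiff(names(samples), "weight"), drop = FALSE])
  breaks_list <- resolve_grid(grid_spec, ncol(cvs))
  dens <- purrr::map(checkpoints, function(ck) {
    weighted_histogram(cvs[1:ck, , drop = FALSE], w[1:ck], breaks_list)$density
  })
  ref_d <- if (reference == "initial") dens[[1]] else dens[[length(dens)]]
  rmsds <- purrr::map_dbl(dens, function(d) {
    support <- d > 0 | ref_d > 0
    if (!any(support)) return(0)
    sqrt(mean((d[support] - ref_d[support])^2))
  })
  tibble(checkpoint = seq_along(checkpoints), n_frames = checkpoints, rmsd = rmsds)
}
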