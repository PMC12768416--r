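# Essential dynamics: trajectory PCA, projections, cosine content,
# covariance overlap and block-convergence diagnostics.

#' Essential-dynamics PCA of a trajectory
#'
#' Frames are superposed onto a reference over the selection, the covariance
#' of the flattened Calpha displacements about the trajectory mean is formed
#' (sample covariance, denominator n - 1), and eigendecomposed with descending
#' eigenvalues (Angstrom^2). Eigenvectors are sign-fixed so the
#' largest-magnitude component is positive.
#'
#' @param traj A `cd_trajectory` with at least 2 frames.
#' @param sel Atom indices entering the covariance (default: Calpha atoms when
#'   the template has them, else all atoms).
#' @param reference Reference coordinates for superposition (default: first
#'   frame).
#' @param n_components Eigenpairs to keep (default 20).
#' @param superpose Superpose frames before the covariance (default TRUE).
#' @param frames Optional subset of frame indices to use.
#' @return A `cd_pca`: `values` (descending eigenvalues), `vectors`
#'   (orthonormal columns), `variance_fraction`, `total_variance`,
#'   `mean_coords`, `sel`, `reference`, `n_frames_used`.
#' @export
fit_pca <- function(traj, sel = NULL, reference = NULL, n_components = 20,
                    superpose = TRUE, frames = NULL) {
  frames <- frames %||% seq_len(n_frames(traj))
  if (length(frames) < 2) stop_confdyn("PCA needs at least 2 frames", "bad_input")
  sel <- sel %||% (if (any(traj$template$atoms$name == "CA"))
    select_atoms(traj, name = "calpha") else seq_len(nrow(traj$template$atoms)))
  ref <- if (is.null(reference)) traj$frames[, , frames[1]] else coords(reference)
  x <- matrix(0, length(frames), 3 * length(sel))
  for (i in seq_along(frames)) {
    fr <- traj$frames[, , frames[i]]
    if (superpose) fr <- superpose(fr, ref, sel = sel)$coords
    x[i, ] <- flatten_coords(fr[sel, , drop = FALSE])
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (length(frames) - 1)
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  k <- min(n_components, length(vals))
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(vecs[, j]))
    if (vecs[i0, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(values = vals[seq_len(k)], vectors = vecs,
                 variance_fraction = if (total > 0) vals[seq_len(k)] / total
                                     else rep(0, k),
                 total_variance = total, mean_coords = unflatten_coords(mu),
                 sel = sel, reference = ref, n_frames_used = length(frames)),
            class = "cd_pca")
}

#' @export
print.cd_pca <- function(x, ...) {
  cat("<cd_pca>", length(x$values), "components from", x$n_frames_used, "frames\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", head(x$variance_fraction, 5)), collapse = ", "),
      if (length(x$values) > 5) "...\n" else "\n")
  invisible(x)
}

#' Project a trajectory onto principal components
#'
#' Frames are superposed exactly as during the fit, and the displacement from
#' the PCA mean is dotted with each unit component vector.
#'
#' @param traj A `cd_trajectory` on the same atom set as the fit.
#' @param pcmodel A `cd_pca` from [fit_pca()].
#' @param components Component indices (default 1:2).
#' @return A tibble with `frame` and one `pc<k>` column per component
#'   (Angstrom).
#' @export
project_trajectory <- function(traj, pcmodel, components = 1:2) {
  sel <- pcmodel$sel
  if (3 * length(sel) != nrow(pcmodel$vectors))
    stop_confdyn("selection does not match component dimension", "bad_input")
  mu <- flatten_coords(pcmodel$mean_coords)
  v <- pcmodel$vectors[, components, drop = FALSE]
  nf <- n_frames(traj)
  proj <- t(vapply(seq_len(nf), function(i) {
    fr <- superpose(traj$frames[, , i], pcmodel$reference, sel = sel)$coords
    as.vector(crossprod(v, flatten_coords(fr[sel, , drop = FALSE]) - mu))
  }, numeric(length(components))))
  if (length(components) == 1) proj <- matrix(proj, ncol = 1)
  colnames(proj) <- paste0("pc", components)
  dplyr::bind_cols(tibble(frame = seq_len(nf)), as_tibble(proj))
}

#' Overlaps of principal components with normal modes
#'
#' [vector_overlap()] of unit PCs with unit non-trivial modes, signs under the
#' shared largest-component-positive convention.
#'
#' @param pcmodel A `cd_pca`.
#' @param modes A `cd_modes` on the same Calpha set.
#' @param components PC indices (default 1:2).
#' @param mode_indices Mode indices (default 1:3).
#' @return A long tibble with `pc`, `mode`, `overlap`.
#' @export
pc_onto_modes <- function(pcmodel, modes, components = 1:2, mode_indices = 1:3) {
  if (nrow(pcmodel$vectors) != nrow(modes$vectors))
    stop_confdyn("PC and mode atom sets differ", "bad_input")
  grid <- expand.grid(pc = components, mode = mode_indices)
  grid$overlap <- mapply(function(p, m)
    vector_overlap(pcmodel$vectors[, p], modes$vectors[, m]),
    grid$pc, grid$mode)
  as_tibble(grid)
}

#' Cosine content of a time series
#'
#' Overlap of a (mean-centred) series with a cosine of `order` half-periods
#' over its duration:
#' `c_i = (2/T) (integral cos(i pi t / T) p(t) dt)^2 / integral p(t)^2 dt`,
#' evaluated by trapezoidal quadrature. Values near 1 indicate
#' random-diffusion-like (unconverged) sampling of the component.
#'
#' @param series Numeric series of length >= 4.
#' @param order Cosine order i (default 1).
#' @param dt Time step (cancels; kept for clarity).
#' @return Cosine content in `[0, 1]`.
#' @export
cosine_content <- function(series, order = 1, dt = 1) {
  n <- length(series)
  if (n < 4) stop_confdyn("series too short", "bad_input")
  p <- series - mean(series)
  t <- (seq_len(n) - 1) * dt
  T <- (n - 1) * dt
  denom <- trapz(t, p^2)
  if (denom == 0) stop_confdyn("constant series: cosine content undefined", "zero_variance")
  num <- trapz(t, cos(order * pi * t / T) * p)
  (2 / T) * num^2 / denom
}

# Extract (values, vectors) from cd_pca / cd_modes / plain lists.
as_cov_model <- function(x, n_components = NULL) {
  if (inherits(x, "cd_pca") || inherits(x, "cd_modes"))
    m <- list(values = x$values, vectors = x$vectors)
  else if (is.list(x) && all(c("values", "vectors") %in% names(x)))
    m <- x
  else stop_confdyn("not a covariance model", "bad_input")
  if (!is.null(n_components)) {
    k <- min(n_components, length(m$values))
    m$values <- m$values[seq_len(k)]
    m$vectors <- m$vectors[, seq_len(k), drop = FALSE]
  }
  m
}

#' Covariance overlap of two fluctuation models
#'
#' `Omega = 1 - sqrt((sum_i (la_i + lb_i) - 2 sum_ij sqrt(la_i lb_j)
#' (va_i . vb_j)^2) / sum_i (la_i + lb_i))`; 1 means identical fluctuation
#' spaces. Models are truncated to their leading `n_components` eigenpairs.
#'
#' @param a,b `cd_pca`, `cd_modes` or lists with `values` and `vectors`.
#' @param n_components Truncation (default 20).
#' @return Overlap in `[0, 1]`.
#' @export
covariance_overlap <- function(a, b, n_components = 20) {
  ma <- as_cov_model(a, n_components); mb <- as_cov_model(b, n_components)
  if (nrow(ma$vectors) != nrow(mb$vectors))
    stop_confdyn("model dimensions differ", "bad_input")
  la <- pmax(ma$values, 0); lb <- pmax(mb$values, 0)
  tot <- sum(la) + sum(lb)
  if (tot == 0) stop_confdyn("all-zero eigenvalues", "zero_variance")
  # numerator evaluated as the Frobenius norm of sqrt(A) - sqrt(B): equal to
  # sum(la) + sum(lb) - 2 sum_ij sqrt(la_i lb_j)(va_i . vb_j)^2 but free of
  # the catastrophic cancellation that form suffers for near-identical models
  sa <- ma$vectors %*% (sqrt(la) * t(ma$vectors))
  sb <- mb$vectors %*% (sqrt(lb) * t(mb$vectors))
  num <- sum((sa - sb)^2)
  1 - sqrt(num / tot)
}

#' Bootstrap-normalised block covariance overlap convergence
#'
#' For each block length L the trajectory is cut into non-overlapping
#' contiguous blocks; the mean covariance overlap of per-block PCA against the
#' full-trajectory PCA is divided by a bootstrap baseline (mean overlap of L
#' frames sampled with replacement against the full model, over `n_boot`
#' draws), removing the finite-sample bias. The inverse of the normalised
#' curve is fitted with `f(L) = c0 - sum_{k=1..3} a_k exp(-L / t_k)`
#' (multi-start nonlinear least squares) and the convergence time is the
#' smallest L whose fitted value is within `epsilon` of the plateau `c0`.
#'
#' @param traj A `cd_trajectory`.
#' @param block_lengths Increasing block lengths (frames); max must be at most
#'   `n_frames / 2`.
#' @param n_boot Bootstrap draws per length (>= 10, default 20).
#' @param sel,reference Passed to [fit_pca()].
#' @param n_components Truncation for the overlaps (default 20).
#' @param epsilon Plateau tolerance defining convergence (default 0.05).
#' @param seed RNG seed for the bootstrap.
#' @return A `cd_bcom`: `curve` (tibble: block_length, block_overlap,
#'   boot_overlap, normalized, inverse, fitted), `fit` (coefficients or NULL),
#'   `fit_ok`, `convergence_time` (frames; NA if the fit failed or no L
#'   reaches the plateau).
#' @export
bcom_convergence <- function(traj, block_lengths, n_boot = 20, sel = NULL,
                             reference = NULL, n_components = 20,
                             epsilon = 0.05, seed = NULL) {
  nf <- n_frames(traj)
  block_lengths <- sort(unique(as.integer(block_lengths)))
  if (max(block_lengths) > nf / 2)
    stop_confdyn("max block length exceeds n_frames / 2", "bad_input")
  if (n_boot < 10) stop_confdyn("n_boot must be >= 10", "bad_input")
  full <- fit_pca(traj, sel = sel, reference = reference,
                  n_components = n_components)
  with_local_seed(seed, {
    rows <- purrr::map(block_lengths, function(L) {
      starts <- seq(1, nf - L + 1, by = L)
      blocks <- vapply(starts, function(s) {
        covariance_overlap(
          fit_pca(traj, sel = sel, reference = reference,
                  n_components = n_components, frames = s:(s + L - 1)),
          full, n_components = n_components)
      }, 0)
      boots <- vapply(seq_len(n_boot), function(b) {
        covariance_overlap(
          fit_pca(traj, sel = sel, reference = reference,
                  n_components = n_components,
                  frames = sample.int(nf, L, replace = TRUE)),
          full, n_components = n_components)
      }, 0)
      tibble(block_length = L, block_overlap = mean(blocks),
             boot_overlap = mean(boots), n_blocks = length(starts),
             boot_sd = sd(boots))
    })
    curve <- bind_rows(rows)
    curve$normalized <- curve$block_overlap / curve$boot_overlap
    curve$inverse <- 1 / curve$normalized
    fit <- fit_triple_exponential(curve$block_length, curve$inverse)
    curve$fitted <- if (!is.null(fit)) triple_exp_eval(fit, curve$block_length)
                    else NA_real_
    conv_time <- NA_real_
    if (!is.null(fit)) {
      grid <- seq(1, 50 * max(curve$block_length), length.out = 20000)
      within <- abs(triple_exp_eval(fit, grid) - fit["c0"]) <= epsilon
      if (any(within)) conv_time <- grid[which(within)[1]]
    }
    structure(list(curve = curve, fit = fit, fit_ok = !is.null(fit),
                   convergence_time = conv_time, epsilon = epsilon),
              class = "cd_bcom")
  })
}

triple_exp_eval <- function(p, L) {
  p["c0"] - p["a1"] * exp(-L / p["t1"]) - p["a2"] * exp(-L / p["t2"]) -
    p["a3"] * exp(-L / p["t3"])
}

# Multi-start (8 log-spaced timescale sets) Levenberg-Marquardt fit of
# c0 - sum a_k exp(-L/t_k); returns named coefficients or NULL on failure.
fit_triple_exponential <- function(L, y, n_starts = 8) {
  span <- max(L) / min(L)
  best <- NULL; best_ss <- Inf
  for (s in seq_len(n_starts)) {
    t1 <- min(L) * span^((s - 1) / n_starts)
    start <- list(c0 = max(y), a1 = (max(y) - min(y)) / 3,
                  a2 = (max(y) - min(y)) / 3, a3 = (max(y) - min(y)) / 3,
                  t1 = t1, t2 = t1 * 3, t3 = t1 * 9)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ c0 - a1 * exp(-L / t1) - a2 * exp(-L / t2) - a3 * exp(-L / t3),
        data = data.frame(L = L, y = y), start = start,
        lower = c(c0 = -Inf, a1 = -Inf, a2 = -Inf, a3 = -Inf,
                  t1 = 1e-6, t2 = 1e-6, t3 = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      ss <- sum(stats::resid(fit)^2)
      if (is.finite(ss) && ss < best_ss) { best_ss <- ss; best <- stats::coef(fit) }
    }
  }
  best
}

#' @export
print.cd_bcom <- function(x, ...) {
  cat("<cd_bcom>", nrow(x$curve), "block lengths; fit",
      if (x$fit_ok) "ok" else "FAILED", "\n")
  if (!is.na(x$convergence_time))
    cat("  estimated convergence time:", signif(x$convergence_time, 4), "frames\n")
  invisible(x)
}
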