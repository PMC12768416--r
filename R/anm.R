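# Anisotropic network model: Hessian assembly, normal modes, overlaps.

#' Build the ANM Hessian of an elastic network
#'
#' Calpha nodes within `cutoff` of each other are joined by springs of
#' stiffness `k_spring`. The off-diagonal 3x3 super-element for a connected
#' pair (i, j) is `-(k_spring / r_ij^2) * d_ij %o% d_ij` with `d_ij` the
#' displacement vector, and each diagonal super-element is minus the sum of
#' the off-diagonals in its row.
#'
#' @param x Coordinates (n x 3 matrix or structure) of the network nodes.
#' @param cutoff Interaction cutoff in Angstrom (default 15).
#' @param k_spring Spring constant (dimensionless, default 1.0).
#' @return A symmetric 3n x 3n matrix.
#' @export
build_hessian <- function(x, cutoff = 15, k_spring = 1.0) {
  xyz <- coords(x)
  n <- nrow(xyz)
  if (n < 2) stop_confdyn("need at least 2 nodes", "bad_input")
  if (cutoff <= 0) stop_confdyn("cutoff must be positive", "bad_input")
  d <- as.matrix(dist(xyz))
  if (any(d[upper.tri(d)] < 1e-8))
    stop_confdyn("coincident nodes give singular springs", "singular_spring")
  h <- matrix(0, 3 * n, 3 * n)
  pairs <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dij <- xyz[j, ] - xyz[i, ]
    block <- -(k_spring / sum(dij^2)) * tcrossprod(dij)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    h[ri, rj] <- block
    h[rj, ri] <- block
    h[ri, ri] <- h[ri, ri] - block
    h[rj, rj] <- h[rj, rj] - block
  }
  h
}

#' Diagonalise a Hessian into a normal-mode set
#'
#' Eigenpairs are ordered by ascending eigenvalue; near-zero (rigid-body)
#' modes are identified by `eigenvalue < zero_tol * max(eigenvalue)` and
#' excluded from the non-trivial mode numbering, so mode 1 is the 7th
#' eigenpair of a connected network. Each eigenvector is sign-fixed so its
#' largest-magnitude component is positive.
#'
#' @param hessian Symmetric 3n x 3n matrix from [build_hessian()].
#' @param n_modes Number of non-trivial modes to keep (default 20).
#' @param zero_tol Relative threshold for zero modes (default 1e-6).
#' @param reference Optional node coordinates stored with the modes (needed by
#'   downstream deformation/projection).
#' @param cutoff,k_spring Metadata recorded with the mode set.
#' @return A `cd_modes` object with fields `values` (non-trivial eigenvalues,
#'   ascending), `vectors` (orthonormal 3n x n_modes), `n_zero`,
#'   `zero_values`, `reference`, `cutoff`, `k_spring`.
#' @export
compute_modes <- function(hessian, n_modes = 20, zero_tol = 1e-6,
                          reference = NULL, cutoff = NA, k_spring = NA) {
  if (!isSymmetric(unname(hessian), tol = 1e-8))
    stop_confdyn("hessian must be symmetric", "bad_input")
  e <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_along(vals)), drop = FALSE]
  lam_max <- max(vals)
  zero <- vals < zero_tol * lam_max
  n_zero <- sum(zero)
  nt <- which(!zero)
  n_modes <- min(n_modes, length(nt))
  keep <- nt[seq_len(n_modes)]
  vectors <- vecs[, keep, drop = FALSE]
  for (k in seq_len(ncol(vectors))) {
    j <- which.max(abs(vectors[, k]))
    if (vectors[j, k] < 0) vectors[, k] <- -vectors[, k]
  }
  structure(list(values = vals[keep], vectors = vectors, n_zero = n_zero,
                 zero_values = vals[zero],
                 reference = if (!is.null(reference)) coords(reference),
                 cutoff = cutoff, k_spring = k_spring),
            class = "cd_modes")
}

#' ANM normal modes of a structure in one step
#'
#' Convenience wrapper: Hessian of the Calpha network, then eigendecomposition.
#'
#' @param x Structure or coordinate matrix. For a `cd_structure`, the Calpha
#'   atoms are selected automatically when present.
#' @param cutoff,k_spring Elastic-network parameters (15 Angstrom, 1.0).
#' @param n_modes Non-trivial modes to keep (default 20).
#' @param zero_tol Relative zero-mode threshold.
#' @return A `cd_modes` object.
#' @export
#' @examples
#' two <- make_two_domain_structure(n_per_domain = 15, linker_length = 5, seed = 1)
#' modes <- anm_modes(two$structure, n_modes = 10)
#' glance(modes)
anm_modes <- function(x, cutoff = 15, k_spring = 1.0, n_modes = 20,
                      zero_tol = 1e-6) {
  xyz <- if (inherits(x, "cd_structure") && any(x$atoms$name == "CA"))
    coords(x)[select_atoms(x, name = "calpha"), , drop = FALSE] else coords(x)
  h <- build_hessian(xyz, cutoff = cutoff, k_spring = k_spring)
  compute_modes(h, n_modes = n_modes, zero_tol = zero_tol, reference = xyz,
                cutoff = cutoff, k_spring = k_spring)
}

#' @export
print.cd_modes <- function(x, ...) {
  cat("<cd_modes>", ncol(x$vectors), "non-trivial modes,", x$n_zero, "zero modes\n")
  cat("  eigenvalues:", paste(signif(head(x$values, 5), 4), collapse = ", "),
      if (length(x$values) > 5) "...\n" else "\n")
  invisible(x)
}

#' Extract one mode as a displacement vector or matrix
#'
#' @param modes A `cd_modes` or `cd_pca` object.
#' @param k Non-trivial mode index (mode 1 is the first non-rigid mode).
#' @param as_matrix Return an n x 3 matrix instead of a 3n vector.
#' @return Unit displacement vector (3n) or matrix (n x 3).
#' @export
mode_vector <- function(modes, k, as_matrix = FALSE) {
  v <- modes$vectors[, k]
  if (as_matrix) unflatten_coords(v) else v
}

#' Normalised overlap of two displacement vectors
#'
#' Dot product of the unit-normalised vectors, in `[-1, 1]`.
#'
#' @param a,b Numeric vectors of equal length and nonzero norm.
#' @return Scalar overlap.
#' @export
vector_overlap <- function(a, b) {
  if (length(a) != length(b)) stop_confdyn("vector dimensions differ", "bad_input")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop_confdyn("zero vector has no direction", "zero_vector")
  sum(a * b) / (na * nb)
}

#' Per-residue square fluctuations of one mode
#'
#' The squared norm of the mode's 3-vector at each residue divided by the mode
#' eigenvalue, plus the unit-sum normalised profile.
#'
#' @param modes A `cd_modes` object.
#' @param mode_index Non-trivial mode index.
#' @return A tibble with `residue`, `sq_fluct`, `normalized`.
#' @export
mode_square_fluctuations <- function(modes, mode_index) {
  if (mode_index < 1 || mode_index > ncol(modes$vectors))
    stop_confdyn("mode index out of range", "bad_input")
  lam <- modes$values[mode_index]
  if (lam <= 0) stop_confdyn("rigid-body mode has no fluctuation", "rigid_mode")
  v <- unflatten_coords(modes$vectors[, mode_index])
  sq <- rowSums(v^2) / lam
  tibble(residue = seq_len(nrow(v)), sq_fluct = sq, normalized = sq / sum(sq))
}

#' Write modes in a plain text (NMD-style) format
#'
#' First line `coordinates x1 y1 z1 ...`, then one line per mode:
#' `mode k eigenvalue c1 c2 ... c3n`.
#'
#' @param modes A `cd_modes` object with reference coordinates.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_modes <- function(modes, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(modes$reference))
    writeLines(paste("coordinates",
                     paste(sprintf("%.3f", flatten_coords(modes$reference)),
                           collapse = " ")), con)
  for (k in seq_along(modes$values))
    writeLines(paste("mode", k, sprintf("%.10g", modes$values[k]),
                     paste(sprintf("%.8f", modes$vectors[, k]), collapse = " ")), con)
  invisible(path)
}

#' Read modes written by [write_modes()]
#'
#' @param path Path to the mode file.
#' @return A `cd_modes` object (with `n_zero = NA`).
#' @export
read_modes <- function(path) {
  lines <- readLines(path)
  ref <- NULL
  if (startsWith(lines[1], "coordinates")) {
    ref <- unflatten_coords(as.numeric(strsplit(lines[1], "\\s+")[[1]][-1]))
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "\\s+")
  vals <- vapply(parts, function(p) as.numeric(p[3]), 0)
  vecs <- vapply(parts, function(p) as.numeric(p[-(1:3)]), numeric(length(parts[[1]]) - 3))
  structure(list(values = vals, vectors = vecs, n_zero = NA_integer_,
                 zero_values = numeric(), reference = ref,
                 cutoff = NA, k_spring = NA), class = "cd_modes")
}
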