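# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant times temperature
#'
#' kT in kJ/mol at a given temperature. The gas constant is
#' 0.008314462618 kJ/(mol K).
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kJ/mol.
#' @export
#' @examples
#' kT(300)
kT <- function(temperature = 300) 0.008314462618 * temperature

# Trapezoidal quadrature on possibly non-uniform abscissae.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# log(sum(exp(x))) without overflow.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise logsumexp of a (small K) x N matrix, vectorised over columns.
col_logsumexp <- function(m) {
  rows <- asplit(m, 1)
  mx <- Reduce(pmax, rows)
  s <- Reduce(`+`, lapply(rows, function(r) exp(r - mx)))
  mx + log(s)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Flatten an n x 3 coordinate matrix to a 3n vector (x1,y1,z1,x2,...),
# matching the Hessian block layout, and back.
flatten_coords <- function(coords) as.vector(t(coords))

unflatten_coords <- function(v) matrix(v, ncol = 3, byrow = TRUE)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal basis (3n x 6) of rigid-body displacements (3 translations,
# 3 infinitesimal rotations about the centroid) of a coordinate set.
rigid_body_basis <- function(coords) {
  n <- nrow(coords)
  centered <- sweep(coords, 2, colMeans(coords))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    disp <- t(apply(centered, 1, function(r) cross3(axes[, k], r)))
    basis[, 3 + k] <- flatten_coords(disp)
  }
  qr.Q(qr(basis))[, seq_len(qr(basis)$rank), drop = FALSE]
}

# Remove the rigid-body component of a set of 3n displacement vectors
# (columns), then re-orthonormalise. Columns that vanish are dropped.
project_out_rigid <- function(vectors, coords) {
  rb <- rigid_body_basis(coords)
  v <- vectors - rb %*% crossprod(rb, vectors)
  q <- qr(v)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

stop_confdyn <- function(msg, class) {
  rlang::abort(msg, class = paste0("confdyn_", class))
}
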