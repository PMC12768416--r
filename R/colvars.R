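# Geometric collective variables: membrane-plane distances, tilt cosine,
# contact counts, pair distances, sugar-ring polar angles, DRMSD, restraint
# energies, bound-state segmentation and dihedral series.

#' Define a membrane reference frame
#'
#' The plane offset is the mean projection of the phosphate-head positions
#' onto the membrane normal. When `leaflet` is `"lower"` or `"upper"` only
#' phosphates below/above the bilayer midplane (mean projection of all of
#' them) enter the average, resolving the leaflet ambiguity of "the average
#' plane of the phosphate heads".
#'
#' @param phosphates n x 3 coordinates of phosphate head atoms.
#' @param normal Membrane normal (default +z); normalised internally.
#' @param leaflet `"both"` (default), `"lower"` or `"upper"`.
#' @return A `cd_membrane_frame` with `normal` (unit) and `plane_offset`
#'   (Angstrom).
#' @export
membrane_frame <- function(phosphates, normal = c(0, 0, 1), leaflet = "both") {
  nrm <- normal / sqrt(sum(normal^2))
  proj <- as.vector(coords(phosphates) %*% nrm)
  if (leaflet != "both") {
    mid <- mean(proj)
    keep <- if (leaflet == "lower") proj < mid else proj > mid
    if (!any(keep)) stop_confdyn("empty leaflet selection", "empty_selection")
    proj <- proj[keep]
  }
  structure(list(normal = nrm, plane_offset = mean(proj)),
            class = "cd_membrane_frame")
}

#' Signed distance from the membrane plane
#'
#' `point . normal - plane_offset`; positive on the +normal side. This is the
#' geometry behind the membrane-distance variables (acceptor-domain anchor
#' d_A, donor-domain anchor d_D, lipid head d_M).
#'
#' @param points A 3-vector or n x 3 matrix.
#' @param frame A `cd_membrane_frame`.
#' @return Signed distance(s) in Angstrom.
#' @export
plane_distance <- function(points, frame) {
  if (is.vector(points)) points <- matrix(points, 1)
  as.vector(points %*% frame$normal) - frame$plane_offset
}

#' Tilt cosine of an internal vector against the membrane normal
#'
#' Cosine of the angle between the normalised vector from atom `a` to atom
#' `b` and the membrane normal. Reporting the cosine keeps the tilt angle in
#' the 0-180 degree range.
#'
#' @param a,b 3-vectors (distinct points).
#' @param frame A `cd_membrane_frame`.
#' @return Cosine in `[-1, 1]`.
#' @export
tilt_cosine <- function(a, b, frame) {
  v <- b - a
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop_confdyn("coincident atoms define no direction", "zero_vector")
  sum(v / nv * frame$normal)
}

#' Smooth contact count between two atom groups
#'
#' Sum over all inter-group pairs of the rational switching function
#' `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)`, with the removable singularity
#' at `r = r0` evaluated as the limit `n/m`. A coincident pair (r = 0) is
#' capped at 1 with a warning.
#'
#' @param group_a,group_b Coordinate matrices.
#' @param r0 Switching distance in Angstrom (default 6).
#' @param n,m Switching exponents (defaults 6, 12).
#' @return Non-negative scalar.
#' @export
contact_count <- function(group_a, group_b, r0 = 6, n = 6, m = 12) {
  a <- coords(group_a); b <- coords(group_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop_confdyn("empty group", "empty_selection")
  if (r0 <= 0) stop_confdyn("r0 must be positive", "bad_input")
  r2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  r <- sqrt(pmax(r2, 0))
  x <- r / r0
  s <- ifelse(abs(x - 1) < 1e-9, n / m, (1 - x^n) / (1 - x^m))
  if (any(r == 0)) {
    rlang::warn("coincident pair in contact_count; capped at 1")
    s[r == 0] <- 1
  }
  sum(s)
}

#' Distance between two groups
#'
#' Euclidean distance between selected points or centroids: the named binding
#' distances (sugar C6 to Lys307 NZ, reactive oxygen to the Asp157 carboxylate
#' carbon, lipid phosphorus to a binding-region centre of mass) are all
#' instances of the three modes.
#'
#' @param group_a,group_b 3-vectors or coordinate matrices.
#' @param mode `"atom-atom"`, `"atom-com"` or `"com-com"`.
#' @return Distance in Angstrom.
#' @export
pair_distance <- function(group_a, group_b, mode = c("atom-atom", "atom-com", "com-com")) {
  mode <- match.arg(mode)
  a <- if (is.vector(group_a)) matrix(group_a, 1) else coords(group_a)
  b <- if (is.vector(group_b)) matrix(group_b, 1) else coords(group_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop_confdyn("empty selection", "empty_selection")
  pa <- if (mode == "com-com") colMeans(a) else a[1, ]
  pb <- if (mode == "atom-atom") b[1, ] else colMeans(b)
  sqrt(sum((pa - pb)^2))
}

# Ring normal = axis of smallest spread of the centred ring atoms.
ring_normal <- function(ring) {
  ctr <- sweep(ring, 2, colMeans(ring))
  if (qr(ctr)$rank < 2) stop_confdyn("collinear ring atoms", "degenerate")
  e <- eigen(crossprod(ctr), symmetric = TRUE)
  e$vectors[, 3]
}

#' Polar angles of a sugar-ring normal in a domain's inertia frame
#'
#' Each frame is superposed onto the reference over the domain Calpha
#' selection; the transformed ring atoms define a best-fit plane whose normal
#' is expressed in the reference inertia-axes basis (see [inertia_axes()]).
#' `gamma` is the polar angle from the largest-moment axis and `theta` the
#' azimuth in the plane of the other two axes. The normal's sign is fixed so
#' `gamma <= 90` degrees at the first frame and propagated by continuity.
#'
#' @param traj A `cd_trajectory` (or a single n x 3 frame).
#' @param ring_idx Indices of the >= 3 non-collinear ring atoms.
#' @param domain_sel Indices of the domain Calpha atoms used for alignment
#'   and whose reference conformation defines the inertia axes.
#' @param reference Reference coordinates (default: first frame).
#' @return A tibble with `frame`, `gamma`, `theta` (degrees; `gamma` in
#'   `[0, 180]`, `theta` in `(-180, 180]`).
#' @export
ring_polar_angles <- function(traj, ring_idx, domain_sel, reference = NULL) {
  single <- !inherits(traj, "cd_trajectory")
  if (single) {
    frames_arr <- array(coords(traj), dim = c(nrow(coords(traj)), 3, 1))
  } else frames_arr <- traj$frames
  ref <- if (is.null(reference)) frames_arr[, , 1] else coords(reference)
  axes <- inertia_axes(ref[domain_sel, , drop = FALSE])
  nf <- dim(frames_arr)[3]
  gamma <- theta <- numeric(nf)
  prev <- NULL
  for (i in seq_len(nf)) {
    fit <- superpose(frames_arr[, , i], ref, sel = domain_sel)$coords
    nrm <- ring_normal(fit[ring_idx, , drop = FALSE])
    if (is.null(prev)) {
      if (sum(nrm * axes[, 3]) < 0) nrm <- -nrm
    } else if (sum(nrm * prev) < 0) nrm <- -nrm
    prev <- nrm
    comp <- as.vector(crossprod(axes, nrm))
    gamma[i] <- acos(max(-1, min(1, comp[3]))) * 180 / pi
    theta[i] <- atan2(comp[2], comp[1]) * 180 / pi
  }
  tibble(frame = seq_len(nf), gamma = gamma, theta = theta)
}

#' Distance root-mean-square deviation over a pair list
#'
#' `sqrt(mean((d_ij - d_ij_ref)^2))` over the listed atom pairs;
#' superposition-free by construction, hence invariant under rigid motions of
#' either input.
#'
#' @param x,reference n x 3 coordinate matrices.
#' @param pairs Two-column integer matrix of atom index pairs.
#' @return DRMSD in Angstrom.
#' @export
drmsd <- function(x, reference, pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) stop_confdyn("empty pair list", "bad_input")
  xc <- coords(x); rc <- coords(reference)
  if (max(pairs) > nrow(xc) || max(pairs) > nrow(rc) || min(pairs) < 1)
    stop_confdyn("pair indices out of range", "bad_input")
  d1 <- sqrt(rowSums((xc[pairs[, 1], , drop = FALSE] - xc[pairs[, 2], , drop = FALSE])^2))
  d2 <- sqrt(rowSums((rc[pairs[, 1], , drop = FALSE] - rc[pairs[, 2], , drop = FALSE])^2))
  sqrt(mean((d1 - d2)^2))
}

#' Upper-wall restraint specification
#'
#' Energy `kappa * max(0, s - s0)^exponent` above the wall, zero below; used
#' e.g. to cap the DRMSD of a docked moiety.
#'
#' @param s0 Wall position (units of the restrained variable).
#' @param kappa Force constant (energy units; >= 0).
#' @param exponent Wall exponent (default 2).
#' @return A `cd_restraint` of kind `"upper_wall"`.
#' @export
upper_wall_restraint <- function(s0, kappa, exponent = 2) {
  if (kappa < 0) stop_confdyn("kappa must be >= 0", "bad_input")
  structure(list(kind = "upper_wall", s0 = s0, kappa = kappa,
                 exponent = exponent), class = "cd_restraint")
}

#' Funnel restraint specification
#'
#' Cone-plus-cylinder boundary: at height `z` along the axis the allowed
#' radius is `R_cyl` for `z >= z_cc` and `R_cyl + (z_cc - z) * tan(alpha)`
#' below; the energy is `kappa * max(0, rho - R(z))^2` with `rho` the radial
#' distance from the axis. Confines a ligand near its site while allowing
#' partial unbinding.
#'
#' @param axis_point Point on the funnel axis.
#' @param axis_dir Axis direction (normalised internally).
#' @param alpha Cone half-angle in degrees, in (0, 90).
#' @param r_cyl Cylinder radius (Angstrom, > 0).
#' @param z_cc Cone-to-cylinder switching height (Angstrom).
#' @param kappa Force constant (>= 0).
#' @return A `cd_restraint` of kind `"funnel"`.
#' @export
funnel_restraint <- function(axis_point, axis_dir, alpha, r_cyl, z_cc, kappa) {
  if (kappa < 0) stop_confdyn("kappa must be >= 0", "bad_input")
  if (r_cyl <= 0) stop_confdyn("r_cyl must be > 0", "bad_input")
  if (alpha <= 0 || alpha >= 90) stop_confdyn("alpha must be in (0, 90) degrees", "bad_input")
  structure(list(kind = "funnel", axis_point = axis_point,
                 axis_dir = axis_dir / sqrt(sum(axis_dir^2)), alpha = alpha,
                 r_cyl = r_cyl, z_cc = z_cc, kappa = kappa),
            class = "cd_restraint")
}

#' Restraint energy
#'
#' Evaluates an upper-wall restraint at scalar variable values, or a funnel
#' restraint at 3D positions. Non-negative everywhere, exactly zero inside the
#' allowed region; a position on the funnel axis is fine (`rho = 0`).
#'
#' @param spec A `cd_restraint`.
#' @param x Numeric vector of variable values (upper wall) or a 3-vector /
#'   n x 3 matrix of positions (funnel).
#' @return Energy (same units as `kappa`), vectorised over inputs.
#' @export
restraint_energy <- function(spec, x) {
  if (!inherits(spec, "cd_restraint")) stop_confdyn("not a restraint spec", "bad_input")
  if (spec$kind == "upper_wall") {
    return(spec$kappa * pmax(0, x - spec$s0)^spec$exponent)
  }
  if (is.vector(x)) x <- matrix(x, 1)
  rel <- sweep(x, 2, spec$axis_point)
  z <- as.vector(rel %*% spec$axis_dir)
  radial <- rel - outer(z, spec$axis_dir)
  rho <- sqrt(rowSums(radial^2))
  rz <- ifelse(z >= spec$z_cc, spec$r_cyl,
               spec$r_cyl + (spec$z_cc - z) * tan(spec$alpha * pi / 180))
  spec$kappa * pmax(0, rho - rz)^2
}

#' Segment a distance series into bound and unbound stretches
#'
#' Frames with value strictly below `threshold` are labelled bound; contiguous
#' bound runs are reported with the overall bound fraction. The default
#' threshold is 40 Angstrom (4 nm).
#'
#' @param values Numeric distance series (Angstrom).
#' @param threshold Bound threshold (default 40).
#' @return A list with `fraction` and `segments` (tibble: start, end).
#' @export
bound_segments <- function(values, threshold = 40) {
  if (length(values) == 0) stop_confdyn("empty series", "empty_input")
  bound <- values < threshold
  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- tibble(start = starts[r$values], end = ends[r$values])
  list(fraction = mean(bound), segments = seg)
}

# Signed dihedral (degrees) for one frame and one atom quadruple.
dihedral_one <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop_confdyn("collinear atoms: dihedral undefined", "degenerate")
  b2u <- b2 / sqrt(sum(b2^2))
  m <- cross3(n1, b2u)
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Dihedral-angle time series
#'
#' Signed dihedrals in `(-180, 180]` degrees via the standard atan2
#' construction, e.g. for glycosidic (phi, psi) pairs.
#'
#' @param traj A `cd_trajectory` (or single n x 3 frame).
#' @param quads A length-4 integer vector or a matrix with 4 columns, one row
#'   per dihedral.
#' @return A tibble with `frame`, `dihedral` (label) and `angle` (degrees).
#' @export
torsion_series <- function(traj, quads) {
  if (is.vector(quads)) quads <- matrix(quads, 1)
  if (ncol(quads) != 4 || any(apply(quads, 1, anyDuplicated) > 0))
    stop_confdyn("each dihedral needs 4 distinct atoms", "bad_input")
  frames_arr <- if (inherits(traj, "cd_trajectory")) traj$frames
    else array(coords(traj), dim = c(nrow(coords(traj)), 3, 1))
  nf <- dim(frames_arr)[3]
  out <- list()
  for (q in seq_len(nrow(quads))) {
    ang <- vapply(seq_len(nf), function(i) {
      fr <- frames_arr[, , i]
      dihedral_one(fr[quads[q, 1], ], fr[quads[q, 2], ],
                   fr[quads[q, 3], ], fr[quads[q, 4], ])
    }, 0)
    out[[q]] <- tibble(frame = seq_len(nf), dihedral = q, angle = ang)
  }
  bind_rows(out)
}

#' Read / write COLVAR-style whitespace tables
#'
#' Tabular files with a `#! FIELDS time cv...` header line, the dialect used
#' for collective-variable and bias time series.
#'
#' @param path File path.
#' @return A tibble with the named columns.
#' @export
read_colvar <- function(path) {
  if (!file.exists(path)) stop_confdyn(paste("no such file:", path), "io")
  first <- readLines(path, n = 1)
  if (!grepl("^#!\\s*FIELDS", first)) stop_confdyn("missing #! FIELDS header", "parse")
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", first), "\\s+")[[1]]
  dat <- utils::read.table(path, comment.char = "#")
  names(dat) <- fields
  as_tibble(dat)
}

#' @rdname read_colvar
#' @param x A data frame to write.
#' @export
write_colvar <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(x), collapse = " ")), con)
  utils::write.table(x, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
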