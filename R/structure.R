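#' Protein structure and trajectory containers
#'
#' A `cd_structure` stores one conformation as an atom table plus coordinates;
#' a `cd_trajectory` stores an atom template and a stack of coordinate frames
#' with identical atom order. All lengths are in Angstrom and author (PDB)
#' residue numbering is kept as-is, never renumbered.
#'
#' @param atoms A data frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`, `element`.
#' @param title Optional title string.
#' @return A `cd_structure` object.
#' @export
cd_structure <- function(atoms, title = "") {
  atoms <- as_tibble(atoms)
  required <- c("serial", "name", "resname", "chain", "resno", "x", "y", "z", "element")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop_confdyn(paste("missing atom columns:", paste(missing, collapse = ", ")), "bad_input")
  if (nrow(atoms) < 1) stop_confdyn("a structure needs at least one atom", "empty_input")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop_confdyn("non-finite coordinates", "bad_input")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop_confdyn("duplicate (chain, residue, atom-name) records", "bad_input")
  structure(list(atoms = atoms, title = title), class = "cd_structure")
}

#' @export
print.cd_structure <- function(x, ...) {
  cat("<cd_structure>", x$title, "\n")
  cat(" ", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  invisible(x)
}

#' Build a trajectory from a template structure and coordinate frames
#'
#' @param template A `cd_structure` giving atom identities.
#' @param frames A list of n_atoms x 3 coordinate matrices, or a 3D array
#'   `[n_atoms, 3, n_frames]`.
#' @param frame_spacing Time per frame (arbitrary units, metadata only).
#' @return A `cd_trajectory` object.
#' @export
cd_trajectory <- function(template, frames, frame_spacing = 1) {
  stopifnot(inherits(template, "cd_structure"))
  n <- nrow(template$atoms)
  if (is.list(frames)) {
    frames <- array(unlist(frames), dim = c(n, 3, length(frames)))
  }
  if (length(dim(frames)) != 3 || dim(frames)[1] != n || dim(frames)[2] != 3)
    stop_confdyn("frames must be n_atoms x 3 x n_frames", "bad_input")
  if (dim(frames)[3] < 1) stop_confdyn("a trajectory needs at least one frame", "empty_input")
  structure(list(template = template, frames = frames, frame_spacing = frame_spacing),
            class = "cd_trajectory")
}

#' @export
print.cd_trajectory <- function(x, ...) {
  cat("<cd_trajectory>", n_frames(x), "frames x", nrow(x$template$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract coordinates
#'
#' @param x A `cd_structure`, `cd_trajectory` or numeric matrix.
#' @param frame Frame index for trajectories.
#' @return An n x 3 coordinate matrix (Angstrom).
#' @export
coords <- function(x, frame = 1) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "cd_structure")) return(as.matrix(x$atoms[, c("x", "y", "z")]))
  if (inherits(x, "cd_trajectory")) return(x$frames[, , frame])
  stop_confdyn("cannot extract coordinates from this object", "bad_input")
}

#' Select atoms by name, residue range and chain
#'
#' Resolves a predicate to a strictly increasing index vector against a
#' structure. Hydrogens are excluded from the `"calpha"` and `"backbone"`
#' shortcuts even when present.
#'
#' @param x A `cd_structure` (or the template of a `cd_trajectory`).
#' @param name Atom-name set (e.g. `"CA"`), or one of the shortcuts
#'   `"calpha"`, `"backbone"`.
#' @param resno Integer vector of residue numbers to keep.
#' @param chain Chain identifiers to keep.
#' @return Sorted integer atom indices.
#' @export
select_atoms <- function(x, name = NULL, resno = NULL, chain = NULL) {
  if (inherits(x, "cd_trajectory")) x <- x$template
  at <- x$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(name)) {
    nm <- if (identical(name, "calpha")) "CA"
          else if (identical(name, "backbone")) c("N", "CA", "C", "O")
          else name
    keep <- keep & at$name %in% nm
  }
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  idx <- which(keep)
  if (length(idx) == 0) stop_confdyn("selection resolves to zero atoms", "empty_selection")
  idx
}

#' Define non-overlapping residue-range domains
#'
#' @param ... Named integer vectors of residue numbers, e.g.
#'   `acceptor = c(13:203, 362:385)`, `donor = 222:352`.
#' @return A named list of residue vectors with class `cd_domains`.
#' @export
#' @examples
#' domain_definition(acceptor = c(13:203, 362:385), donor = 222:352,
#'                   linkers = c(204:221, 353:361))
domain_definition <- function(...) {
  doms <- list(...)
  if (is.null(names(doms)) || any(names(doms) == ""))
    stop_confdyn("every domain must be named", "bad_input")
  all_res <- unlist(doms)
  if (any(all_res <= 0)) stop_confdyn("residue numbers must be positive", "bad_input")
  if (anyDuplicated(all_res)) stop_confdyn("domain residue ranges overlap", "bad_input")
  structure(doms, class = "cd_domains")
}

# ---- PDB / XYZ I/O (PDB parsing and writing delegate to bio3d) ----

#' Read a PDB file
#'
#' Fixed-column PDB v3.3 ATOM/HETATM records; MODEL/ENDMDL blocks yield a
#' trajectory. Alternate locations other than `''`/`'A'` are dropped with a
#' warning.
#'
#' @param path Path to a PDB file.
#' @param model Optional model number; forces a single-structure return.
#' @return A `cd_structure` (single model) or `cd_trajectory` (several).
#' @export
read_pdb <- function(path, model = NULL) {
  if (!file.exists(path)) stop_confdyn(paste("no such file:", path), "io")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop_confdyn(paste("PDB parse failure:", conditionMessage(e)), "parse"))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop_confdyn("no atoms in file", "empty_input")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  if (!all(keep)) {
    rlang::warn(sprintf("dropping %d alternate-location atoms", sum(!keep)))
  }
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  atoms <- tibble(
    serial = at$eleno, name = at$elety, resname = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain), resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), at$elesy))
  atoms <- atoms[keep, ]
  xyz_idx <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
  xyz <- xyz[, xyz_idx, drop = FALSE]
  template <- cd_structure(atoms, title = basename(path))
  nm <- nrow(xyz)
  if (!is.null(model)) {
    if (model < 1 || model > nm) stop_confdyn("model index out of range", "bad_input")
    template$atoms[, c("x", "y", "z")] <- as.data.frame(unflatten_coords(xyz[model, ]))
    return(template)
  }
  if (nm == 1) return(template)
  frames <- array(0, dim = c(nrow(atoms), 3, nm))
  for (i in seq_len(nm)) frames[, , i] <- unflatten_coords(xyz[i, ])
  cd_trajectory(template, frames)
}

#' Write a trajectory (or structure) as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, coordinates rounded to 3 decimals.
#'
#' @param traj A `cd_trajectory` or `cd_structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ensemble_pdb <- function(traj, path) {
  if (inherits(traj, "cd_structure")) traj <- cd_trajectory(traj, list(coords(traj)))
  at <- traj$template$atoms
  nf <- n_frames(traj)
  xyz <- t(apply(traj$frames, 3, flatten_coords))
  if (nf == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = round(xyz, 3),
                   type = rep("ATOM", nrow(at)),
                   eleno = at$serial, elety = at$name, resid = at$resname,
                   chain = at$chain, resno = at$resno, elesy = at$element)
  invisible(path)
}

#' Read a plain multi-frame XYZ file
#'
#' Per frame: atom count, comment line, then `element x y z` rows.
#'
#' @param path Path to an XYZ file.
#' @return A `cd_trajectory` (or `cd_structure` for a single frame).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop_confdyn(paste("no such file:", path), "io")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); elements <- NULL; i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_confdyn(sprintf("bad atom count at line %d", i), "parse")
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop_confdyn(sprintf("bad coordinates near line %d", i + 2), "parse")
    elements <- elements %||% el
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop_confdyn("no frames in file", "empty_input")
  n <- length(elements)
  template <- cd_structure(tibble(
    serial = seq_len(n), name = elements, resname = "UNK", chain = "A",
    resno = seq_len(n),
    x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
    element = elements), title = basename(path))
  if (length(frames) == 1) return(template)
  cd_trajectory(template, frames)
}

#' Write a trajectory as plain XYZ
#'
#' @param traj A `cd_trajectory` or `cd_structure`.
#' @param path Output path.
#' @param comment Comment line written per frame.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(traj, path, comment = "confdyn") {
  if (inherits(traj, "cd_structure")) traj <- cd_trajectory(traj, list(coords(traj)))
  el <- traj$template$atoms$element
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$frames[, , i]
    writeLines(c(as.character(length(el)), comment,
                 sprintf("%s %.6f %.6f %.6f", el, xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

# ---- superposition / RMSD / RMSF / inertia ----

#' Root-mean-square deviation between two coordinate sets
#'
#' Computed as-is, without superposition.
#'
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  a <- coords(a); b <- coords(b)
  if (!all(dim(a) == dim(b))) stop_confdyn("coordinate dimensions differ", "bad_input")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1, reflections rejected) and
#' translation minimising the RMSD of `mobile` onto `reference` over a
#' selection, applies it to all mobile atoms, and reports the RMSD over the
#' selection.
#'
#' @param mobile,reference n x 3 coordinate matrices (or structures) with
#'   matching atom order.
#' @param sel Integer indices of the atoms to fit (default: all). At least 3
#'   non-collinear atoms are required.
#' @return A list with `coords` (transformed mobile set), `rmsd` (Angstrom,
#'   over the selection), `rotation` (3 x 3) and `translation` (length 3),
#'   such that `transformed = mobile %*% t(rotation) + translation`.
#' @export
superpose <- function(mobile, reference, sel = NULL) {
  m <- coords(mobile); r <- coords(reference)
  if (!all(dim(m) == dim(r))) stop_confdyn("coordinate dimensions differ", "bad_input")
  sel <- sel %||% seq_len(nrow(m))
  if (length(sel) < 3) stop_confdyn("need at least 3 atoms to superpose", "degenerate")
  p <- m[sel, , drop = FALSE]; q <- r[sel, , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  pm <- sweep(p, 2, pc); qm <- sweep(q, 2, qc)
  if (qr(qm)$rank < 2 || qr(pm)$rank < 2)
    stop_confdyn("collinear selection: superposition is degenerate", "degenerate")
  h <- crossprod(pm, qm)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- qc - as.vector(rot %*% pc)
  out <- m %*% t(rot) + matrix(trans, nrow(m), 3, byrow = TRUE)
  list(coords = out, rmsd = rmsd(out[sel, , drop = FALSE], q),
       rotation = rot, translation = trans)
}

#' Per-atom root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` after optional superposition of
#' every frame onto a reference.
#'
#' @param traj A `cd_trajectory` with at least 2 frames.
#' @param sel Atom indices to report (default: all).
#' @param superpose_sel Atom indices used to fit frames onto `reference`
#'   first; `NULL` assumes frames are already superposed.
#' @param reference Reference coordinates for the fit (default: first frame).
#' @param normalize If `TRUE`, divide by the maximum over the selection so the
#'   peak equals 1.
#' @return A tibble with `atom`, `resno`, `rmsf`.
#' @export
rmsf <- function(traj, sel = NULL, superpose_sel = NULL, reference = NULL,
                 normalize = FALSE) {
  if (n_frames(traj) < 2)
    stop_confdyn("fluctuations are undefined for a single frame", "bad_input")
  sel <- sel %||% seq_len(nrow(traj$template$atoms))
  ref <- if (is.null(reference)) traj$frames[, , 1] else coords(reference)
  nf <- n_frames(traj)
  stack <- array(0, dim = c(length(sel), 3, nf))
  for (i in seq_len(nf)) {
    fr <- traj$frames[, , i]
    if (!is.null(superpose_sel)) fr <- superpose(fr, ref, sel = superpose_sel)$coords
    stack[, , i] <- fr[sel, , drop = FALSE]
  }
  mean_xyz <- apply(stack, c(1, 2), mean)
  dev2 <- sweep(stack, c(1, 2), mean_xyz)^2
  vals <- sqrt(apply(dev2, 1, sum) / nf)
  if (normalize) vals <- vals / max(vals)
  tibble(atom = sel, resno = traj$template$atoms$resno[sel], rmsf = vals)
}

#' Principal axes of inertia
#'
#' Eigenvectors of the unit-mass inertia tensor about the centroid, ordered by
#' ascending principal moment. Each axis is flipped so its largest-magnitude
#' component is positive; if the resulting triad is left-handed the
#' largest-moment axis is flipped back to restore a right-handed set.
#'
#' @param x A coordinate matrix or structure with at least 3 non-collinear
#'   points.
#' @return A 3 x 3 matrix whose columns are the axes (ascending moment), with
#'   the moments in attribute `"moments"`.
#' @export
inertia_axes <- function(x) {
  xyz <- coords(x)
  if (nrow(xyz) < 3) stop_confdyn("need at least 3 points", "degenerate")
  c0 <- sweep(xyz, 2, colMeans(xyz))
  if (qr(c0)$rank < 2) stop_confdyn("collinear points: axes are degenerate", "degenerate")
  iT <- diag(3) * sum(rowSums(c0^2)) - crossprod(c0)
  e <- eigen(iT, symmetric = TRUE)
  ord <- order(e$values)
  axes <- e$vectors[, ord, drop = FALSE]
  moments <- e$values[ord]
  for (k in 1:3) {
    j <- which.max(abs(axes[, k]))
    if (axes[j, k] < 0) axes[, k] <- -axes[, k]
  }
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  attr(axes, "moments") <- moments
  axes
}
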