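# Mode-guided iterative ensemble generation (deform / cluster / relax cycles)
# with per-domain distortion statistics and mode-space projections.

#' Deform a conformation along normal modes to an exact RMSD
#'
#' The displacement is a random linear combination of the selected mode
#' vectors with coefficients drawn uniformly on the unit sphere in
#' mode-coefficient space, scaled so the Calpha RMSD from the input equals
#' `target_rmsd` exactly (for an orthonormal mode basis,
#' `RMSD = |coefficients| / sqrt(n_atoms)`).
#'
#' @param conformer n x 3 coordinate matrix (the mode node set).
#' @param modes A `cd_modes` object computed on the same node set.
#' @param mode_indices Non-trivial mode indices to combine (default 1:2).
#' @param target_rmsd Target Calpha RMSD in Angstrom.
#' @param seed Optional RNG seed.
#' @param coefficients Optional fixed coefficient vector (overrides the random
#'   draw; scaled to the target unless all zero).
#' @return The deformed n x 3 coordinate matrix.
#' @export
deform_to_rmsd <- function(conformer, modes, mode_indices = c(1, 2),
                           target_rmsd = 1.0, seed = NULL, coefficients = NULL) {
  if (length(mode_indices) == 0) stop_confdyn("empty mode list", "bad_input")
  if (target_rmsd < 0) stop_confdyn("target_rmsd must be >= 0", "bad_input")
  xyz <- coords(conformer)
  v <- modes$vectors[, mode_indices, drop = FALSE]
  if (nrow(v) != 3 * nrow(xyz))
    stop_confdyn("mode dimension does not match conformer", "bad_input")
  cf <- coefficients %||% with_local_seed(seed, rnorm(length(mode_indices)))
  nc <- sqrt(sum(cf^2))
  if (nc == 0) return(xyz)
  cf <- cf / nc * target_rmsd * sqrt(nrow(xyz))
  xyz + unflatten_coords(as.vector(v %*% cf))
}

#' Linear cluster-count schedule
#'
#' @param n_generations Number of generations.
#' @param from,by Start and increment of the linear ramp (defaults 10, 10, so
#'   generation g holds `10 * g` clusters).
#' @return Integer vector of per-generation cluster counts.
#' @export
generation_schedule <- function(n_generations, from = 10, by = 10) {
  s <- from + by * (seq_len(n_generations) - 1)
  if (any(s <= 0) || any(diff(s) < 0))
    stop_confdyn("schedule must be positive and non-decreasing", "bad_input")
  s
}

# Pairwise Calpha RMSD matrix after optimal superposition of every pair.
pairwise_rmsd <- function(conf_list) {
  n <- length(conf_list)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- superpose(conf_list[[j]], conf_list[[i]])$rmsd
  }
  d
}

#' Identity relaxer
#'
#' Returns conformers unchanged; useful for bookkeeping tests and when only
#' the mode-space geometry matters.
#'
#' @return A relaxer function `f(coords) -> coords`.
#' @export
relaxer_identity <- function() function(xyz) xyz

#' Elastic-network relaxer
#'
#' Monotone steepest-descent minimiser of the ANM elastic energy
#' `sum_pairs k/2 (r - r0)^2` over the reference network (pairs within
#' `cutoff` in the reference), plus a soft-sphere clash penalty
#' `k_clash * (r_clash - r)^2` for non-bonded pairs closer than `r_clash`.
#' Backtracking line search guarantees the energy never increases.
#'
#' @param reference Reference node coordinates defining the network topology
#'   and rest lengths.
#' @param cutoff Network cutoff in Angstrom (default 15).
#' @param k_spring Spring constant (default 1).
#' @param r_clash Clash radius in Angstrom (default 3).
#' @param k_clash Clash stiffness (default 10).
#' @param n_steps Maximum descent steps (default 50).
#' @param step0 Initial step size (default 0.1).
#' @return A relaxer function `f(coords) -> coords` with attribute
#'   `"energy"` giving the energy function used.
#' @export
relaxer_elastic <- function(reference, cutoff = 15, k_spring = 1,
                            r_clash = 3, k_clash = 10, n_steps = 50, step0 = 0.1) {
  ref <- coords(reference)
  dref <- as.matrix(dist(ref))
  net <- which(upper.tri(dref) & dref <= cutoff, arr.ind = TRUE)
  r0 <- dref[net]
  energy <- function(xyz) {
    dv <- xyz[net[, 1], , drop = FALSE] - xyz[net[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    e <- sum(k_spring / 2 * (r - r0)^2)
    dall <- as.matrix(dist(xyz))
    close <- which(upper.tri(dall) & dall < r_clash, arr.ind = TRUE)
    if (nrow(close) > 0) {
      bonded <- paste(net[, 1], net[, 2])
      lab <- paste(close[, 1], close[, 2])
      extra <- !(lab %in% bonded)
      if (any(extra)) {
        rc <- dall[close[extra, , drop = FALSE]]
        e <- e + sum(k_clash * (r_clash - rc)^2)
      }
    }
    e
  }
  accumulate_pairs <- function(g, idx, gpair) {
    rs <- rowsum(rbind(gpair, -gpair), c(idx[, 1], idx[, 2]))
    rows <- as.integer(rownames(rs))
    g[rows, ] <- g[rows, ] + rs
    g
  }
  gradient <- function(xyz) {
    g <- matrix(0, nrow(xyz), 3)
    dv <- xyz[net[, 1], , drop = FALSE] - xyz[net[, 2], , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    g <- accumulate_pairs(g, net, dv * (k_spring * (r - r0) / pmax(r, 1e-12)))
    dall <- as.matrix(dist(xyz))
    close <- which(upper.tri(dall) & dall < r_clash, arr.ind = TRUE)
    if (nrow(close) > 0) {
      bonded <- paste(net[, 1], net[, 2])
      close <- close[!(paste(close[, 1], close[, 2]) %in% bonded), , drop = FALSE]
      if (nrow(close) > 0) {
        dvc <- xyz[close[, 1], , drop = FALSE] - xyz[close[, 2], , drop = FALSE]
        rc <- sqrt(rowSums(dvc^2))
        g <- accumulate_pairs(g, close, dvc * (-2 * k_clash * (r_clash - rc) / pmax(rc, 1e-12)))
      }
    }
    g
  }
  f <- function(xyz) {
    e <- energy(xyz)
    step <- step0
    for (it in seq_len(n_steps)) {
      g <- gradient(xyz)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-10) break
      accepted <- FALSE
      for (ls in 1:20) {
        trial <- xyz - step * g / gn
        et <- energy(trial)
        if (et <= e) { xyz <- trial; e <- et; accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      step <- min(step * 1.5, 1)
    }
    xyz
  }
  attr(f, "energy") <- energy
  f
}

#' Run iterative deform / cluster / relax generations
#'
#' Per generation g the current representatives are each deformed into
#' children (children per parent is `ceiling(2 * schedule[g] / n_parents)`),
#' the pooled children are clustered into `schedule[g]` groups by pairwise
#' Calpha RMSD (k-medoids, [cluster::pam()]), each medoid is relaxed with the
#' supplied relaxer, and the relaxed medoids seed the next generation. All
#' relaxed medoids accumulate into the ensemble. Deterministic under a fixed
#' seed and relaxer.
#'
#' @param start Starting structure or Calpha coordinate matrix.
#' @param modes A `cd_modes` computed on the start's Calpha set.
#' @param mode_indices Modes defining the deformation vectors (default 1:2).
#' @param n_generations Number of generations (study default 50).
#' @param target_rmsd Per-generation deformation RMSD in Angstrom (default 1).
#' @param schedule Per-generation cluster counts; default
#'   `generation_schedule(n_generations)` (10, 20, ..., 10 * n).
#' @param relaxer Relaxer function; default [relaxer_identity()].
#' @param seed RNG seed.
#' @return A `cd_ensemble`: list with `conformers` (n x 3 x total array),
#'   `info` (tibble: conformer, generation, parent, pre_relax_rmsd),
#'   `reference`, `modes_used`, `target_rmsd`.
#' @export
run_generations <- function(start, modes, mode_indices = c(1, 2),
                            n_generations = 5, target_rmsd = 1.0,
                            schedule = NULL, relaxer = relaxer_identity(),
                            seed = NULL) {
  ref <- if (inherits(start, "cd_structure") && any(start$atoms$name == "CA"))
    coords(start)[select_atoms(start, name = "calpha"), , drop = FALSE] else coords(start)
  schedule <- schedule %||% generation_schedule(n_generations)
  if (length(schedule) != n_generations)
    stop_confdyn("schedule length must equal n_generations", "bad_input")
  with_local_seed(seed, {
    parents <- list(ref)
    all_conf <- list(); info <- list()
    for (g in seq_len(n_generations)) {
      n_child <- ceiling(2 * schedule[g] / length(parents))
      children <- list(); child_parent <- integer(); child_rmsd <- numeric()
      for (p in seq_along(parents)) {
        for (cc in seq_len(n_child)) {
          child <- deform_to_rmsd(parents[[p]], modes, mode_indices, target_rmsd)
          children[[length(children) + 1]] <- child
          child_parent <- c(child_parent, p)
          child_rmsd <- c(child_rmsd, rmsd(child, parents[[p]]))
        }
      }
      if (length(children) > schedule[g]) {
        dmat <- pairwise_rmsd(children)
        med <- cluster::pam(stats::as.dist(dmat), k = schedule[g],
                            diss = TRUE, pamonce = 5)$id.med
      } else med <- seq_along(children)
      relaxed <- list(); kept_parent <- integer(); kept_rmsd <- numeric()
      for (m in med) {
        rx <- tryCatch(relaxer(children[[m]]), error = function(e) NULL)
        if (is.null(rx)) {
          rlang::warn(sprintf("relaxer failed on a generation-%d conformer; dropped", g))
          next
        }
        relaxed[[length(relaxed) + 1]] <- rx
        kept_parent <- c(kept_parent, child_parent[m])
        kept_rmsd <- c(kept_rmsd, child_rmsd[m])
      }
      if (length(relaxed) == 0)
        stop_confdyn(sprintf("all conformers of generation %d failed relaxation", g), "relax")
      for (i in seq_along(relaxed)) {
        all_conf[[length(all_conf) + 1]] <- relaxed[[i]]
        info[[length(info) + 1]] <- tibble(
          generation = g, parent = kept_parent[i], pre_relax_rmsd = kept_rmsd[i])
      }
      parents <- relaxed
    }
    conf_arr <- array(unlist(all_conf), dim = c(nrow(ref), 3, length(all_conf)))
    info <- bind_rows(info)
    info$conformer <- seq_len(nrow(info))
    structure(list(conformers = conf_arr,
                   info = info[, c("conformer", "generation", "parent", "pre_relax_rmsd")],
                   reference = ref, modes_used = mode_indices,
                   target_rmsd = target_rmsd, schedule = schedule),
              class = "cd_ensemble")
  })
}

#' @export
print.cd_ensemble <- function(x, ...) {
  cat("<cd_ensemble>", dim(x$conformers)[3], "conformers over",
      max(x$info$generation), "generations\n")
  invisible(x)
}

#' Convert an ensemble to a trajectory
#'
#' @param ensemble A `cd_ensemble`.
#' @return A `cd_trajectory` over the ensemble's Calpha nodes.
#' @export
ensemble_as_trajectory <- function(ensemble) {
  n <- nrow(ensemble$reference)
  template <- cd_structure(tibble(
    serial = seq_len(n), name = "CA", resname = "ALA", chain = "A",
    resno = seq_len(n), x = ensemble$reference[, 1],
    y = ensemble$reference[, 2], z = ensemble$reference[, 3], element = "C"))
  cd_trajectory(template, ensemble$conformers)
}

#' Per-domain distortion fractions of an ensemble
#'
#' For each domain, every conformer's domain Calpha set is superposed onto the
#' reference domain and the domain RMSD computed; the fraction of conformers
#' exceeding `threshold` is reported.
#'
#' @param ensemble A `cd_ensemble`.
#' @param domains A `cd_domains` (residue numbers index the Calpha nodes of
#'   the reference in order).
#' @param threshold RMSD threshold in Angstrom (default 2).
#' @return A tibble with `domain`, `n_exceed`, `n_total`, `fraction`.
#' @export
domain_distortion <- function(ensemble, domains, threshold = 2.0) {
  n_atoms <- nrow(ensemble$reference)
  nc <- dim(ensemble$conformers)[3]
  out <- purrr::imap(unclass(domains), function(res, nm) {
    idx <- intersect(res, seq_len(n_atoms))
    if (length(idx) == 0) stop_confdyn(paste("empty domain selection:", nm), "empty_selection")
    rms <- vapply(seq_len(nc), function(i) {
      superpose(ensemble$conformers[idx, , i], ensemble$reference[idx, , drop = FALSE])$rmsd
    }, 0)
    tibble(domain = nm, n_exceed = sum(rms > threshold), n_total = nc,
           fraction = mean(rms > threshold))
  })
  bind_rows(out)
}

#' Project ensemble conformers into normal-mode space
#'
#' Each conformer is superposed onto the mode reference (all Calpha), the
#' flattened displacement is dotted with each unit mode vector, and the
#' coordinates (Angstrom) are returned per conformer.
#'
#' @param ensemble A `cd_ensemble`.
#' @param modes A `cd_modes` whose reference matches the ensemble reference.
#' @param mode_indices Modes to project onto (default 1:3).
#' @return A tibble with `conformer`, `generation` and one `nm<k>` column per
#'   requested mode.
#' @export
project_ensemble <- function(ensemble, modes, mode_indices = 1:3) {
  if (nrow(modes$vectors) != 3 * nrow(ensemble$reference))
    stop_confdyn("mode dimension does not match ensemble atoms", "bad_input")
  v <- modes$vectors[, mode_indices, drop = FALSE]
  nc <- dim(ensemble$conformers)[3]
  proj <- t(vapply(seq_len(nc), function(i) {
    fit <- superpose(ensemble$conformers[, , i], ensemble$reference)$coords
    as.vector(crossprod(v, flatten_coords(fit - ensemble$reference)))
  }, numeric(length(mode_indices))))
  if (length(mode_indices) == 1) proj <- matrix(proj, ncol = 1)
  colnames(proj) <- paste0("nm", mode_indices)
  dplyr::bind_cols(ensemble$info[, c("conformer", "generation")], as_tibble(proj))
}
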