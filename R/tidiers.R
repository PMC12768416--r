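# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for the
# fitted-object classes.

#' @export
tidy.cd_modes <- function(x, ...) {
  tibble(mode = seq_along(x$values), eigenvalue = x$values)
}

#' @export
glance.cd_modes <- function(x, ...) {
  tibble(n_modes = length(x$values), n_zero = x$n_zero,
         n_atoms = nrow(x$vectors) / 3, cutoff = x$cutoff,
         k_spring = x$k_spring)
}

#' @export
tidy.cd_pca <- function(x, ...) {
  tibble(component = seq_along(x$values), eigenvalue = x$values,
         variance_fraction = x$variance_fraction)
}

#' @export
glance.cd_pca <- function(x, ...) {
  tibble(n_components = length(x$values), n_frames = x$n_frames_used,
         total_variance = x$total_variance,
         pc1_fraction = x$variance_fraction[1])
}

#' @export
tidy.cd_ladder <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.cd_ladder <- function(x, ...) {
  tibble(n_replicas = nrow(x), lambda_min = min(x$lambda),
         lambda_max = max(x$lambda), target = attr(x, "target"),
         mean_acceptance = mean(x$acceptance_to_next, na.rm = TRUE))
}

#' @export
tidy.cd_wham <- function(x, ...) {
  tibble(state = seq_along(x$f), f = x$f)
}

#' @export
glance.cd_wham <- function(x, ...) {
  tibble(n_states = length(x$f), iterations = x$iterations,
         converged = x$converged, ess = x$ess)
}

#' @export
tidy.cd_bcom <- function(x, ...) x$curve

#' @export
glance.cd_bcom <- function(x, ...) {
  tibble(n_lengths = nrow(x$curve), fit_ok = x$fit_ok,
         convergence_time = x$convergence_time, epsilon = x$epsilon)
}

#' Plot a free-energy surface
#'
#' 1D: free-energy profile; 2D: filled raster with masked (unpopulated) bins
#' left blank.
#'
#' @param object A `cd_fes`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_fes <- function(object, ...) {
  d <- as_tibble(object)
  if (!"cv2" %in% names(d)) {
    ggplot2::ggplot(dplyr::filter(d, .data$populated),
                    ggplot2::aes(x = .data$cv1, y = .data$free_energy)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "CV 1", y = "Free energy (kJ/mol)")
  } else {
    ggplot2::ggplot(dplyr::filter(d, .data$populated),
                    ggplot2::aes(x = .data$cv1, y = .data$cv2,
                                 fill = .data$free_energy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)") +
      ggplot2::labs(x = "CV 1", y = "CV 2")
  }
}

#' Plot a block-covariance-overlap convergence curve
#'
#' Normalised overlap ratio against block length, with the fitted curve's
#' inverse when available.
#'
#' @param object A `cd_bcom`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_bcom <- function(object, ...) {
  d <- object$curve
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$block_length,
                                       y = .data$normalized)) +
    ggplot2::geom_point() + ggplot2::geom_line(linetype = 3) +
    ggplot2::labs(x = "Block length (frames)",
                  y = "Bootstrap-normalised covariance overlap")
  if (object$fit_ok)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = 1 / .data$fitted), colour = "red")
  p
}

#' Plot a lambda ladder
#'
#' Rung positions with predicted neighbour acceptances.
#'
#' @param object A `cd_ladder`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_ladder <- function(object, ...) {
  d <- as_tibble(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rung, y = .data$lambda)) +
    ggplot2::geom_step() + ggplot2::geom_point(ggplot2::aes(colour = .data$acceptance_to_next)) +
    ggplot2::scale_colour_viridis_c(name = "Acceptance") +
    ggplot2::labs(x = "Rung", y = expression(lambda))
}

#' Plot replica-exchange diagnostics
#'
#' Occupancy probability matrix as a heatmap.
#'
#' @param object A `cd_replica_diag`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cd_replica_diag <- function(object, ...) {
  occ <- object$occupancy
  d <- as_tibble(as.data.frame.table(occ, responseName = "occupancy"))
  names(d)[1:2] <- c("replica", "state")
  d$replica <- as.integer(as.character(d$replica))
  d$state <- as.integer(factor(d$state))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$replica,
                                  fill = .data$occupancy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Ladder state", y = "Replica")
}

#' Plot per-mode square fluctuations
#'
#' @param modes A `cd_modes`.
#' @param mode_indices Modes to show (default 1:4).
#' @return A ggplot object.
#' @export
plot_mode_fluctuations <- function(modes, mode_indices = 1:4) {
  d <- bind_rows(purrr::map(mode_indices, function(k) {
    mutate(mode_square_fluctuations(modes, k), mode = k)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode, scales = "free_y") +
    ggplot2::labs(x = "Residue", y = "Normalised square fluctuation")
}
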