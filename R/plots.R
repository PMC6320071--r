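#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an idealized trajectory
#'
#' Extension-time record with the decoded state path overlaid as the
#' per-state emission means.
#'
#' @param object An `idealized_trace`.
#' @param max_points Thin the displayed record to at most this many samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.idealized_trace <- function(object, max_points = 20000L, ...) {
  traj <- object$trajectory
  d <- tibble::tibble(
    time_s = traj$time_s,
    extension_nm = traj$extension_nm,
    idealized_nm = object$means_nm[object$state]
  )
  if (nrow(d) > max_points) {
    d <- d[seq(1L, nrow(d), length.out = max_points), ]
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$extension_nm),
                       colour = "grey60", linewidth = 0.2) +
    ggplot2::geom_step(ggplot2::aes(y = .data$idealized_nm),
                       colour = "red", linewidth = 0.5) +
    ggplot2::labs(x = "time (s)", y = "extension (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a Boltzmann occupancy fit
#'
#' Measured unfolded-state occupancies against mean force with the fitted
#' Boltzmann curve evaluated on a fine separation grid.
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  d <- object$data
  D_grid <- seq(min(d$trap_separation_nm), max(d$trap_separation_nm),
                length.out = 60)
  m <- mechanical_energy_difference(
    object$state_folded, object$state_unfolded, object$traps, object$handle,
    D_grid, object$temperature_K
  )
  f_grid <- (dumbbell_equilibrium(object$traps, object$state_folded,
                                  object$handle, D_grid)$force_pN +
             dumbbell_equilibrium(object$traps, object$state_unfolded,
                                  object$handle, D_grid)$force_pN) / 2
  curve <- tibble::tibble(
    force_mean_pN = f_grid,
    occupancy = stats::plogis(m - object$unfolding_energy_kbt)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$force_mean_pN)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$occupancy),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$occupancy_unfolded)) +
    ggplot2::labs(
      x = "mean force (pN)", y = "unfolded occupancy",
      subtitle = sprintf("unfolding energy %.2f +/- %.2f kBT",
                         object$unfolding_energy_kbt, object$se_kbt)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a Kramers rate fit
#'
#' Measured folding and unfolding rates against mean force on a log scale,
#' with the fitted force-dependent rates.
#'
#' @param object A `kramers_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kramers_fit <- function(object, ...) {
  d <- object$data
  long <- tidyr::pivot_longer(
    dplyr::select(d, "force_mean_pN", "folding_rate_per_s",
                  "unfolding_rate_per_s", "folding_rate_fitted",
                  "unfolding_rate_fitted"),
    -"force_mean_pN",
    names_to = "which", values_to = "rate_per_s"
  )
  long$fitted <- grepl("fitted", long$which)
  long$transition <- ifelse(grepl("^folding", long$which), "folding",
                            "unfolding")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$force_mean_pN,
                                     y = .data$rate_per_s,
                                     colour = .data$transition)) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, !.data$fitted)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$fitted)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean force (pN)", y = "rate (1/s)") +
    ggplot2::theme_minimal()
}

#' Plot a force-extension curve from a simulated pull
#'
#' @param pull A `pull_curve` from [simulate_pull()].
#' @param thin Keep every `thin`-th sample for display.
#' @return A ggplot object.
#' @export
plot_fec <- function(pull, thin = 5L) {
  d <- pull[seq(1L, nrow(pull), by = thin), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$extension_nm,
                                  y = .data$force_pN)) +
    ggplot2::geom_path(linewidth = 0.2, colour = "grey30") +
    ggplot2::labs(x = "extension (nm)", y = "force (pN)") +
    ggplot2::theme_minimal()
}
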