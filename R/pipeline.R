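#' Full landscape analysis of a constant-separation trajectory set
#'
#' Chains the analysis stages for one molecule: each trajectory is idealized
#' with the two-state hidden Markov model, dwell statistics are collected,
#' the midpoint force is interpolated, the zero-force unfolding energy is
#' fitted from occupancies (Boltzmann) and the zero-force rates from dwell
#' rates (Kramers), and the midpoint extension change is interpolated from
#' the per-record emission-mean separations.
#'
#' @param trajectories A list of [trajectory()] objects recorded at distinct
#'   constant trap separations.
#' @param state_folded,state_unfolded [construct_state()]s fixing the
#'   mechanical (structural) model of the two states; energies are ignored.
#' @param traps A [trap_pair()].
#' @param handle A [wlc_segment()] DNA handle.
#' @param temperature_K Temperature in kelvin.
#' @param seed Seed forwarded to the idealizer.
#' @param include_rates Also run the Kramers rate fit? Set `FALSE` for
#'   occupancy-only (equilibrium) analyses.
#' @return A list of class `landscape_result`: one-row `summary` tibble
#'   (unfolding energy with SE, zero-force rates, lifetime, equilibrium
#'   force, midpoint extension change), the per-record `stats` tibble, and
#'   the two fit objects.
#' @export
fit_landscape <- function(trajectories, state_folded, state_unfolded,
                          traps = trap_pair(), handle = dna_handle(),
                          temperature_K = 298, seed = 1L,
                          include_rates = TRUE) {
  stats_tbl <- purrr::map_dfr(trajectories, function(tr) {
    dwell_statistics(idealize_two_state(tr, seed = seed))
  })
  usable <- dplyr::filter(stats_tbl, !.data$no_transition)
  bf <- boltzmann_fit(usable, state_folded, state_unfolded, traps, handle,
                      temperature_K)
  kf <- if (include_rates) {
    tryCatch(
      kramers_fit(usable, state_folded, state_unfolded, traps, handle,
                  temperature_K),
      error = function(e) NULL
    )
  } else {
    NULL
  }
  eqf <- tryCatch(equilibrium_force(usable), error = function(e) NULL)
  dx_mid <- if (!is.null(eqf)) {
    ord <- order(usable$force_mean_pN)
    stats::approx(usable$force_mean_pN[ord], usable$delta_x_nm[ord],
                  xout = eqf$equilibrium_force_pN, ties = mean, rule = 2)$y
  } else {
    mean(usable$delta_x_nm)
  }
  summary <- tibble::tibble(
    unfolding_energy_kbt = bf$unfolding_energy_kbt,
    unfolding_energy_se_kbt = bf$se_kbt,
    folding_rate_per_s = if (is.null(kf)) NA_real_ else kf$folding_rate_per_s,
    unfolding_rate_per_s = if (is.null(kf)) NA_real_ else kf$unfolding_rate_per_s,
    lifetime_s = if (is.null(kf)) NA_real_ else 1 / kf$unfolding_rate_per_s,
    equilibrium_force_pN = if (is.null(eqf)) NA_real_ else eqf$equilibrium_force_pN,
    delta_x_midpoint_nm = dx_mid,
    n_records = nrow(usable)
  )
  structure(
    list(summary = summary, stats = stats_tbl, boltzmann = bf, kramers = kf),
    class = "landscape_result"
  )
}

#' @export
print.landscape_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<landscape_result> dV = %.2f +/- %.2f kBT, F_eq = %.2f pN, ",
           "dx = %.2f nm, k_f0 = %.3g /s, k_u0 = %.3g /s (%d records)\n"),
    s$unfolding_energy_kbt, s$unfolding_energy_se_kbt,
    s$equilibrium_force_pN, s$delta_x_midpoint_nm,
    s$folding_rate_per_s, s$unfolding_rate_per_s, s$n_records
  ))
  invisible(x)
}

#' @export
glance.landscape_result <- function(x, ...) x$summary

#' @export
tidy.landscape_result <- function(x, ...) x$stats
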