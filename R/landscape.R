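#' Mechanical free-energy difference between two construct states
#'
#' Zero-protein-energy part of the dumbbell free energy (Eq.-6-type model):
#' for each trap separation, the total system free energy of the folded and
#' unfolded states is evaluated with both state energies set to zero, and
#' the difference (folded minus unfolded) is returned in kBT. Adding the
#' zero-force unfolding energy to this difference gives the full free-energy
#' difference that sets occupancies via the Boltzmann distribution.
#'
#' @param state_folded,state_unfolded [construct_state()]s; their
#'   `energy_kbt` fields are ignored here.
#' @param traps A [trap_pair()].
#' @param handle A [wlc_segment()] for the DNA handle.
#' @param separation_nm Trap separations in nm (vectorised).
#' @param temperature_K Temperature in kelvin.
#' @return Numeric vector, G_mech(folded) - G_mech(unfolded) in kBT.
#' @export
mechanical_energy_difference <- function(state_folded, state_unfolded, traps,
                                         handle, separation_nm,
                                         temperature_K = 298) {
  f0 <- construct_state(state_folded$label, state_folded$unfolded_contour_nm,
                        state_folded$hard_core_nm, 0)
  u0 <- construct_state(state_unfolded$label, state_unfolded$unfolded_contour_nm,
                        state_unfolded$hard_core_nm, 0)
  dumbbell_free_energy(traps, f0, handle, separation_nm, temperature_K) -
    dumbbell_free_energy(traps, u0, handle, separation_nm, temperature_K)
}

#' Zero-force unfolding energy from force-dependent occupancies
#'
#' One-parameter fit of the measured unfolded-state occupancies to the
#' Boltzmann distribution on the dumbbell free energy: the predicted
#' occupancy at separation D is 1/(1 + exp(dV - m(D))), where m(D) is the
#' mechanical free-energy difference (folded minus unfolded, in kBT) of the
#' two states and dV is the zero-force unfolding energy. The fit is a
#' weighted least squares with binomial weights from the observed dwell
#' counts; the standard error comes from the binomial Fisher information.
#'
#' @param stats A tibble of [dwell_statistics()] rows at three or more
#'   distinct trap separations, with columns `trap_separation_nm`,
#'   `occupancy_unfolded` and `n_dwells`.
#' @inheritParams mechanical_energy_difference
#' @return An object of class `boltzmann_fit` with elements
#'   `unfolding_energy_kbt`, `se_kbt`, and a `data` tibble carrying the
#'   mechanical energies and fitted occupancies.
#' @export
boltzmann_fit <- function(stats, state_folded, state_unfolded, traps, handle,
                          temperature_K = 298) {
  stopifnot(all(c("trap_separation_nm", "occupancy_unfolded") %in% names(stats)))
  occ <- stats$occupancy_unfolded
  if (all(occ < 0.02) || all(occ > 0.98)) {
    stop("occupancies are all ~0 or ~1; the unfolding energy is not ",
         "identifiable from this force range", call. = FALSE)
  }
  n <- if ("n_dwells" %in% names(stats)) stats$n_dwells else rep(1, length(occ))
  m <- mechanical_energy_difference(
    state_folded, state_unfolded, traps, handle,
    stats$trap_separation_nm, temperature_K
  )
  ssr <- function(dv) {
    p <- stats::plogis(m - dv)
    w <- n / pmax(p * (1 - p), 1e-6)
    sum(w * (occ - p)^2)
  }
  opt <- stats::optimize(ssr, interval = range(m) + c(-15, 15))
  dv <- opt$minimum
  p_hat <- stats::plogis(m - dv)
  se <- 1 / sqrt(sum(n * p_hat * (1 - p_hat)))
  structure(
    list(
      unfolding_energy_kbt = dv,
      se_kbt = se,
      data = dplyr::mutate(stats,
        mech_energy_kbt = m,
        occupancy_fitted = p_hat
      ),
      state_folded = state_folded,
      state_unfolded = state_unfolded,
      traps = traps,
      handle = handle,
      temperature_K = temperature_K
    ),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> unfolding energy = %.2f +/- %.2f kBT (%d separations)\n",
    x$unfolding_energy_kbt, x$se_kbt, nrow(x$data)
  ))
  invisible(x)
}

#' @export
tidy.boltzmann_fit <- function(x, ...) {
  tibble::tibble(
    term = "unfolding_energy_kbt",
    estimate = x$unfolding_energy_kbt,
    std.error = x$se_kbt
  )
}

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(
    unfolding_energy_kbt = x$unfolding_energy_kbt,
    se_kbt = x$se_kbt,
    n_separations = nrow(x$data)
  )
}

#' Zero-force rates and transition state from force-dependent rates
#'
#' Kramers-type fit of the measured folding and unfolding rates. The
#' transition state is modelled as a construct state on the contour-length
#' coordinate, a fraction `phi` of the way from folded to unfolded (both the
#' released contour and the hard core interpolate linearly), with a single
#' shared attempt-rate prefactor:
#' k_unfold(D) = k_u0 exp(-(m*(D) - m_f(D))) and
#' k_fold(D) = k_f0 exp(-(m*(D) - m_u(D))), where m are mechanical system
#' energies in kBT. At zero tension all mechanical terms vanish, so k_u0 and
#' k_f0 are the zero-force rates. Parameters (log k_f0, log k_u0, phi) are
#' fitted by least squares on log rates; `phi` can be fixed (default
#' behaviour when fewer than three separations carry both rates).
#'
#' @inheritParams boltzmann_fit
#' @param stats Tibble with `trap_separation_nm`, `folding_rate_per_s`,
#'   `unfolding_rate_per_s`.
#' @param fix_position Either `NULL` (fit the barrier position) or a number
#'   in (0, 1) to fix it.
#' @param attempt_rate_per_s Conventional attempt-rate prefactor k_m used to
#'   express the barrier energy; it does not influence the fitted rates.
#' @return An object of class `kramers_fit` with zero-force rates, the
#'   kinetic unfolding energy ln(k_f0/k_u0), the barrier position and
#'   energy, and a `data` tibble with fitted rates.
#' @export
kramers_fit <- function(stats, state_folded, state_unfolded, traps, handle,
                        temperature_K = 298, fix_position = NULL,
                        attempt_rate_per_s = 1e6) {
  ok <- is.finite(stats$folding_rate_per_s) & is.finite(stats$unfolding_rate_per_s)
  d <- stats[ok, ]
  if (nrow(d) < 3L) {
    stop("rates at >= 3 separations are required", call. = FALSE)
  }
  D <- d$trap_separation_nm
  Lf <- state_folded$unfolded_contour_nm
  Lu <- state_unfolded$unfolded_contour_nm
  Hf <- state_folded$hard_core_nm
  Hu <- state_unfolded$hard_core_nm

  mech <- function(phi) {
    ts <- construct_state("barrier", Lf + phi * (Lu - Lf),
                          max(Hf + phi * (Hu - Hf), 0), 0)
    mb <- dumbbell_free_energy(traps, ts, handle, D, temperature_K)
    mf <- dumbbell_free_energy(
      traps, construct_state("f", Lf, Hf, 0), handle, D, temperature_K
    )
    mu <- dumbbell_free_energy(
      traps, construct_state("u", Lu, Hu, 0), handle, D, temperature_K
    )
    list(b = mb, f = mf, u = mu)
  }

  obj <- function(par) {
    phi <- if (is.null(fix_position)) stats::plogis(par[3]) else fix_position
    m <- mech(phi)
    log_ku <- par[1] - (m$b - m$f)
    log_kf <- par[2] - (m$b - m$u)
    sum((log(d$unfolding_rate_per_s) - log_ku)^2) +
      sum((log(d$folding_rate_per_s) - log_kf)^2)
  }
  init <- c(log(mean(d$unfolding_rate_per_s)), log(mean(d$folding_rate_per_s)), 0)
  np <- if (is.null(fix_position)) 3L else 2L
  opt <- stats::optim(init[seq_len(np)], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- opt$par
  phi <- if (is.null(fix_position)) stats::plogis(par[3]) else fix_position
  k_u0 <- exp(par[1])
  k_f0 <- exp(par[2])
  m <- mech(phi)
  structure(
    list(
      folding_rate_per_s = k_f0,
      unfolding_rate_per_s = k_u0,
      unfolding_energy_kinetic_kbt = log(k_f0 / k_u0),
      barrier_position = phi,
      barrier_contour_nm = Lf + phi * (Lu - Lf),
      barrier_energy_kbt = log(attempt_rate_per_s / k_u0),
      attempt_rate_per_s = attempt_rate_per_s,
      data = dplyr::mutate(d,
        folding_rate_fitted = k_f0 * exp(-(m$b - m$u)),
        unfolding_rate_fitted = k_u0 * exp(-(m$b - m$f))
      ),
      convergence = opt$convergence
    ),
    class = "kramers_fit"
  )
}

#' @export
print.kramers_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<kramers_fit> k_f0 = %.3g /s, k_u0 = %.3g /s ",
           "(ln kf/ku = %.2f kBT, barrier at phi = %.2f)\n"),
    x$folding_rate_per_s, x$unfolding_rate_per_s,
    x$unfolding_energy_kinetic_kbt, x$barrier_position
  ))
  invisible(x)
}

#' @export
tidy.kramers_fit <- function(x, ...) {
  tibble::tibble(
    term = c("folding_rate_per_s", "unfolding_rate_per_s",
             "unfolding_energy_kinetic_kbt", "barrier_position",
             "barrier_energy_kbt"),
    estimate = c(x$folding_rate_per_s, x$unfolding_rate_per_s,
                 x$unfolding_energy_kinetic_kbt, x$barrier_position,
                 x$barrier_energy_kbt)
  )
}

#' @export
glance.kramers_fit <- function(x, ...) {
  tibble::tibble(
    folding_rate_per_s = x$folding_rate_per_s,
    unfolding_rate_per_s = x$unfolding_rate_per_s,
    unfolding_energy_kinetic_kbt = x$unfolding_energy_kinetic_kbt,
    lifetime_s = 1 / x$unfolding_rate_per_s,
    n_separations = nrow(x$data)
  )
}

#' Lifetime of the folded state
#'
#' Reciprocal of the unfolding rate.
#'
#' @param unfolding_rate_per_s Unfolding rate in 1/s (> 0), or a
#'   `kramers_fit`.
#' @return Lifetime in seconds.
#' @export
#' @examples
#' lifetime(0.7) # 1.4 s
lifetime <- function(unfolding_rate_per_s) {
  if (inherits(unfolding_rate_per_s, "kramers_fit")) {
    unfolding_rate_per_s <- unfolding_rate_per_s$unfolding_rate_per_s
  }
  stopifnot(unfolding_rate_per_s > 0)
  1 / unfolding_rate_per_s
}

#' Reversible work of the transition at the midpoint
#'
#' Equilibrium force multiplied by the transition extension change,
#' expressed in kBT. This mechanical work exceeds the zero-force unfolding
#' energy by the entropic stretching energy of the polypeptide released at
#' force; the two quantities are reported alongside each other, never
#' conflated.
#'
#' @param equilibrium_force_pN Midpoint force in pN (> 0).
#' @param delta_x_nm Transition extension change in nm (> 0).
#' @param temperature_K Temperature in kelvin.
#' @return Work in kBT.
#' @export
unfolding_work <- function(equilibrium_force_pN, delta_x_nm,
                           temperature_K = 298) {
  stopifnot(equilibrium_force_pN > 0, delta_x_nm >= 0)
  equilibrium_force_pN * delta_x_nm / kbt(temperature_K)
}

#' Aggregate per-molecule landscape results
#'
#' Unweighted mean and standard error of the mean across molecules for every
#' numeric column. A single molecule is returned as-is with `NA` standard
#' errors.
#'
#' @param results Tibble with one row per molecule and numeric result
#'   columns (plus any identifier columns, which are dropped).
#' @return A tibble with columns `quantity`, `mean`, `sem`, `n_molecules`.
#' @export
#' @examples
#' aggregate_molecules(tibble::tibble(unfolding_energy_kbt = c(5.0, 5.2, 5.4)))
aggregate_molecules <- function(results) {
  if (nrow(results) == 0L) stop("empty ensemble", call. = FALSE)
  num <- dplyr::select(results, dplyr::where(is.numeric))
  tidyr::pivot_longer(num, dplyr::everything(),
                      names_to = "quantity", values_to = "value") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sem = if (sum(is.finite(.data$value)) > 1L) {
        stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(is.finite(.data$value)))
      } else {
        NA_real_
      },
      n_molecules = sum(is.finite(.data$value)),
      .groups = "drop"
    )
}
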