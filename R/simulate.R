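#' Two-state simulation scenario
#'
#' Bundles everything needed to simulate constant-trap-separation
#' trajectories and pulling curves of a two-state folding system in the
#' dumbbell geometry: the folded and unfolded construct states (whose
#' `energy_kbt` difference is the zero-force unfolding energy), traps, DNA
#' handle, the zero-force unfolding rate, the barrier position on the
#' contour coordinate, and the measurement-noise model. The zero-force
#' folding rate follows from detailed balance:
#' k_f0 = k_u0 exp(unfolding energy).
#'
#' @param state_folded,state_unfolded [construct_state()]s; the unfolding
#'   energy is `state_unfolded$energy_kbt - state_folded$energy_kbt` and
#'   must be finite.
#' @param traps A [trap_pair()].
#' @param handle A [wlc_segment()] DNA handle.
#' @param unfolding_rate0_per_s Zero-force unfolding rate k_u0 in 1/s.
#' @param barrier_position Fraction of the contour coordinate (0 folded,
#'   1 unfolded) at which the transition state sits.
#' @param noise_sd_nm Gaussian measurement noise on the extension, nm.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param temperature_K Temperature in kelvin.
#' @return An object of class `two_state_scenario`.
#' @export
two_state_scenario <- function(state_folded, state_unfolded, traps = trap_pair(),
                               handle = dna_handle(),
                               unfolding_rate0_per_s = 0.7,
                               barrier_position = 0.5,
                               noise_sd_nm = 1.5, sample_rate_hz = 1000,
                               temperature_K = 298) {
  stopifnot(
    inherits(state_folded, "construct_state"),
    inherits(state_unfolded, "construct_state"),
    unfolding_rate0_per_s > 0,
    barrier_position > 0, barrier_position < 1,
    noise_sd_nm >= 0, sample_rate_hz > 0
  )
  dv <- state_unfolded$energy_kbt - state_folded$energy_kbt
  structure(
    list(
      state_folded = state_folded,
      state_unfolded = state_unfolded,
      traps = traps,
      handle = handle,
      unfolding_energy_kbt = dv,
      unfolding_rate0_per_s = unfolding_rate0_per_s,
      folding_rate0_per_s = unfolding_rate0_per_s * exp(dv),
      barrier_position = barrier_position,
      noise_sd_nm = noise_sd_nm,
      sample_rate_hz = sample_rate_hz,
      temperature_K = temperature_K
    ),
    class = "two_state_scenario"
  )
}

#' @export
print.two_state_scenario <- function(x, ...) {
  cat(sprintf(
    paste0("<two_state_scenario> dV = %.2f kBT, k_f0 = %.3g /s, ",
           "k_u0 = %.3g /s, noise %.2g nm @ %g Hz\n"),
    x$unfolding_energy_kbt, x$folding_rate0_per_s, x$unfolding_rate0_per_s,
    x$noise_sd_nm, x$sample_rate_hz
  ))
  invisible(x)
}

.scenario_barrier_state <- function(scenario) {
  f <- scenario$state_folded
  u <- scenario$state_unfolded
  phi <- scenario$barrier_position
  construct_state(
    "barrier",
    f$unfolded_contour_nm + phi * (u$unfolded_contour_nm - f$unfolded_contour_nm),
    max(f$hard_core_nm + phi * (u$hard_core_nm - f$hard_core_nm), 0),
    0
  )
}

#' Transition rates and state equilibria at a trap separation
#'
#' Evaluates the scenario's Kramers-type force-dependent rates and the
#' per-state mechanical equilibria at the given separations. Rates obey
#' detailed balance with the dumbbell free-energy difference:
#' k_f(D)/k_u(D) = exp(G_folded(D) is lower...) i.e. the stationary
#' occupancies reproduce the Boltzmann distribution at every separation.
#'
#' @param scenario A [two_state_scenario()].
#' @param separation_nm Trap separations in nm.
#' @return A tibble with per-state forces and extensions, the free-energy
#'   difference `delta_g_kbt` (unfolded minus folded, total), and the rates
#'   `folding_rate_per_s`, `unfolding_rate_per_s`.
#' @export
scenario_rates <- function(scenario, separation_nm) {
  s <- scenario
  zero <- function(st) construct_state(st$label, st$unfolded_contour_nm,
                                       st$hard_core_nm, 0)
  mf <- dumbbell_free_energy(s$traps, zero(s$state_folded), s$handle,
                             separation_nm, s$temperature_K)
  mu <- dumbbell_free_energy(s$traps, zero(s$state_unfolded), s$handle,
                             separation_nm, s$temperature_K)
  mb <- dumbbell_free_energy(s$traps, .scenario_barrier_state(s), s$handle,
                             separation_nm, s$temperature_K)
  eq_f <- dumbbell_equilibrium(s$traps, s$state_folded, s$handle,
                               separation_nm, s$temperature_K)
  eq_u <- dumbbell_equilibrium(s$traps, s$state_unfolded, s$handle,
                               separation_nm, s$temperature_K)
  tibble::tibble(
    separation_nm = separation_nm,
    force_folded_pN = eq_f$force_pN,
    force_unfolded_pN = eq_u$force_pN,
    extension_folded_nm = eq_f$extension_nm,
    extension_unfolded_nm = eq_u$extension_nm,
    delta_g_kbt = (mu + s$unfolding_energy_kbt) - mf,
    unfolding_rate_per_s = s$unfolding_rate0_per_s * exp(-(mb - mf)),
    folding_rate_per_s = s$folding_rate0_per_s * exp(-(mb - mu))
  )
}

#' Trap separation at which the scenario has a given mean force
#'
#' Finds D such that the mean of the folded- and unfolded-state equilibrium
#' forces equals the target; vectorised over targets.
#'
#' @param scenario A [two_state_scenario()].
#' @param force_pN Target mean forces in pN.
#' @return Separations in nm.
#' @export
separation_for_mean_force <- function(scenario, force_pN) {
  s <- scenario
  vapply(force_pN, function(f0) {
    lo <- separation_for_force(s$traps, s$state_folded, s$handle,
                               max(f0 - 2, 0.2), s$temperature_K)
    hi <- separation_for_force(s$traps, s$state_unfolded, s$handle, f0 + 2,
                               s$temperature_K)
    stats::uniroot(function(D) {
      eq_f <- dumbbell_equilibrium(s$traps, s$state_folded, s$handle, D,
                                   s$temperature_K)$force_pN
      eq_u <- dumbbell_equilibrium(s$traps, s$state_unfolded, s$handle, D,
                                   s$temperature_K)$force_pN
      (eq_f + eq_u) / 2 - f0
    }, c(lo, hi), tol = 1e-9)$root
  }, numeric(1))
}

#' Simulate a constant-trap-separation extension trajectory
#'
#' Continuous-time (Gillespie) two-state Markov jumps with the scenario's
#' force-dependent rates at the given separation, discretised onto a uniform
#' sampling grid. Each sample's extension is the equilibrium tether
#' extension of the current state plus Gaussian measurement noise; the force
#' channel is derived from the extension through the trap compliance,
#' F = k_traps (D - x), so force and extension fluctuate out of phase as in
#' the instrument.
#'
#' @param scenario A [two_state_scenario()].
#' @param separation_nm Constant relative trap separation in nm.
#' @param duration_s Record length in seconds.
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @return A [trajectory()] whose `metadata` records the ground truth
#'   (state extensions, forces, rates, occupancy).
#' @export
simulate_constant_separation <- function(scenario, separation_nm, duration_s,
                                         seed) {
  stopifnot(duration_s > 0)
  r <- scenario_rates(scenario, separation_nm)
  if (!is.finite(r$delta_g_kbt)) {
    stop("separation outside the solvable range", call. = FALSE)
  }
  k_u <- r$unfolding_rate_per_s
  k_f <- r$folding_rate_per_s
  dt <- 1 / scenario$sample_rate_hz
  n <- floor(duration_s / dt)

  withr::with_seed(seed, {
    p_unfolded <- k_u / (k_u + k_f)
    state0 <- if (stats::runif(1) < p_unfolded) 2L else 1L
    # exact jump times, then discretisation
    jump_times <- numeric(0)
    states <- state0
    t_now <- 0
    cur <- state0
    while (t_now < duration_s) {
      rate <- if (cur == 1L) k_u else k_f
      t_now <- t_now + stats::rexp(1, rate)
      if (t_now >= duration_s) break
      cur <- 3L - cur
      jump_times <- c(jump_times, t_now)
      states <- c(states, cur)
    }
    t_sample <- (seq_len(n) - 0.5) * dt
    state_at <- states[findInterval(t_sample, jump_times) + 1L]
    x_state <- ifelse(state_at == 1L, r$extension_folded_nm,
                      r$extension_unfolded_nm)
    x <- x_state + stats::rnorm(n, 0, scenario$noise_sd_nm)
    force <- trap_stiffness_eff(scenario$traps) * (separation_nm - x)
    trajectory(
      time_s = t_sample,
      extension_nm = x,
      force_pN = force,
      trap_separation_nm = separation_nm,
      metadata = list(
        seed = seed,
        truth = as.list(r),
        occupancy_unfolded_true = p_unfolded
      )
    )
  })
}

#' Simulate a constant-speed pulling or relaxation curve
#'
#' Ramps the trap separation at constant speed while the protein switches
#' between its two states with time-inhomogeneous rates, simulated by
#' thinning against the maximal rate over the ramp. Unfolding events appear
#' as sawtooth rips: an extension jump with a force drop.
#'
#' @param scenario A [two_state_scenario()].
#' @param from_nm,to_nm Start and end separations (relaxation if
#'   `to_nm < from_nm`).
#' @param speed_nm_s Trap speed in nm/s; default 10.
#' @param seed Integer seed.
#' @param grid_points Number of separations at which rates and state
#'   extensions are tabulated for interpolation.
#' @return A tibble of class `pull_curve` with `time_s`, `separation_nm`,
#'   `extension_nm`, `force_pN` and the hidden `state` (1 folded,
#'   2 unfolded).
#' @export
simulate_pull <- function(scenario, from_nm, to_nm, speed_nm_s = 10, seed = 1L,
                          grid_points = 100L) {
  stopifnot(speed_nm_s > 0, from_nm != to_nm)
  duration <- abs(to_nm - from_nm) / speed_nm_s
  dt <- 1 / scenario$sample_rate_hz
  n <- floor(duration / dt)
  direction <- sign(to_nm - from_nm)
  D_grid <- seq(min(from_nm, to_nm), max(from_nm, to_nm),
                length.out = grid_points)
  tab <- scenario_rates(scenario, D_grid)
  ku_at <- stats::approxfun(D_grid, tab$unfolding_rate_per_s)
  kf_at <- stats::approxfun(D_grid, tab$folding_rate_per_s)
  xf_at <- stats::approxfun(D_grid, tab$extension_folded_nm)
  xu_at <- stats::approxfun(D_grid, tab$extension_unfolded_nm)
  rate_max <- max(tab$unfolding_rate_per_s, tab$folding_rate_per_s) * 1.05

  withr::with_seed(seed, {
    t_sample <- (seq_len(n) - 0.5) * dt
    D_t <- from_nm + direction * speed_nm_s * t_sample
    # initial state from local equilibrium at the starting separation
    kf0 <- kf_at(D_t[1])
    ku0 <- ku_at(D_t[1])
    cur <- if (stats::runif(1) < ku0 / (ku0 + kf0)) 2L else 1L
    # thinning: candidate events at the uniform majorant rate
    t_now <- 0
    jumps <- numeric(0)
    states <- cur
    repeat {
      t_now <- t_now + stats::rexp(1, rate_max)
      if (t_now >= duration) break
      D_now <- from_nm + direction * speed_nm_s * t_now
      k <- if (cur == 1L) ku_at(D_now) else kf_at(D_now)
      if (stats::runif(1) < k / rate_max) {
        cur <- 3L - cur
        jumps <- c(jumps, t_now)
        states <- c(states, cur)
      }
    }
    state_at <- states[findInterval(t_sample, jumps) + 1L]
    x_state <- ifelse(state_at == 1L, xf_at(D_t), xu_at(D_t))
    x <- x_state + stats::rnorm(n, 0, scenario$noise_sd_nm)
    force <- trap_stiffness_eff(scenario$traps) * (D_t - x)
    out <- tibble::tibble(
      time_s = t_sample,
      separation_nm = D_t,
      extension_nm = x,
      force_pN = force,
      state = state_at
    )
    class(out) <- c("pull_curve", class(out))
    out
  })
}

#' Simulate trapped-bead Brownian noise
#'
#' Exact discretisation of the Ornstein-Uhlenbeck process describing an
#' overdamped bead in a harmonic trap: stationary variance kBT/k and corner
#' frequency k/(2 pi gamma). Used as a fixture generator for
#' [calibrate_trap_stiffness()].
#'
#' @param stiffness_pN_nm Trap stiffness k in pN/nm.
#' @param drag_pN_s_nm Drag coefficient gamma in pN s/nm.
#' @param rate_hz Sampling rate in Hz.
#' @param duration_s Record length in s.
#' @param seed Integer seed.
#' @param temperature_K Temperature in kelvin.
#' @return A tibble with `time_s` and `position_nm`.
#' @export
simulate_bead_noise <- function(stiffness_pN_nm, drag_pN_s_nm, rate_hz,
                                duration_s, seed, temperature_K = 298) {
  stopifnot(stiffness_pN_nm > 0, drag_pN_s_nm > 0, rate_hz > 0, duration_s > 0)
  n <- floor(duration_s * rate_hz)
  dt <- 1 / rate_hz
  theta <- stiffness_pN_nm / drag_pN_s_nm # relaxation rate, 1/s
  sd_stat <- sqrt(kbt(temperature_K) / stiffness_pN_nm)
  rho <- exp(-theta * dt)
  sd_innov <- sd_stat * sqrt(1 - rho^2)
  withr::with_seed(seed, {
    eps <- stats::rnorm(n)
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd_stat)
    for (i in 2:n) x[i] <- rho * x[i - 1] + sd_innov * eps[i]
    tibble::tibble(time_s = seq_len(n) * dt, position_nm = x)
  })
}

#' Calibrate a two-state scenario against target observables
#'
#' Solves for the contour-length change, the hard-core change and the
#' midpoint trap separation such that, at the midpoint, the dumbbell model
#' reproduces three target observables exactly: the zero-force unfolding
#' energy (equal populations at the midpoint), the mean force, and the
#' extension change between the two states at fixed separation. This makes
#' the generator's ground truth self-consistent with the quantities the
#' downstream pipeline estimates.
#'
#' @param unfolding_energy_kbt Zero-force unfolding energy dV in kBT.
#' @param equilibrium_force_pN Midpoint mean force in pN.
#' @param delta_x_nm Extension change (unfolded minus folded) at the
#'   midpoint separation in nm.
#' @param base_unfolded_contour_nm Contour length of the unfolded state's
#'   disordered polypeptide (sets the absolute state, not the transition).
#' @param base_hard_core_nm Hard-core size of the unfolded state in nm.
#' @inheritParams two_state_scenario
#' @return A [two_state_scenario()] with an extra element
#'   `midpoint_separation_nm`.
#' @export
calibrate_two_state_scenario <- function(unfolding_energy_kbt,
                                         equilibrium_force_pN,
                                         delta_x_nm,
                                         base_unfolded_contour_nm = 50,
                                         base_hard_core_nm = 2,
                                         traps = trap_pair(),
                                         handle = dna_handle(),
                                         unfolding_rate0_per_s = 0.7,
                                         barrier_position = 0.5,
                                         noise_sd_nm = 1.5,
                                         sample_rate_hz = 1000,
                                         temperature_K = 298) {
  Lu <- base_unfolded_contour_nm
  Hu <- base_hard_core_nm
  state_u <- construct_state("unfolded", Lu, Hu, unfolding_energy_kbt)
  objective <- function(par) {
    dL <- par[1]
    dH <- par[2]
    D <- par[3]
    state_f <- construct_state("folded", max(Lu - dL, 1e-6),
                               max(Hu + dH, 0), 0)
    eq_f <- dumbbell_equilibrium(traps, state_f, handle, D, temperature_K)
    eq_u <- dumbbell_equilibrium(traps, state_u, handle, D, temperature_K)
    g_f <- dumbbell_free_energy(traps, state_f, handle, D, temperature_K)
    g_u <- dumbbell_free_energy(traps, state_u, handle, D, temperature_K)
    c(
      g_u - g_f,
      (eq_f$force_pN + eq_u$force_pN) / 2 - equilibrium_force_pN,
      eq_u$extension_nm - eq_f$extension_nm - delta_x_nm
    )
  }
  D0 <- separation_for_force(traps, state_u, handle, equilibrium_force_pN,
                             temperature_K)
  sol <- pracma::fsolve(objective, c(Lu * 0.5, 2, D0), tol = 1e-10)
  if (max(abs(objective(sol$x))) > 1e-6) {
    stop("scenario calibration did not converge", call. = FALSE)
  }
  dL <- sol$x[1]
  dH <- sol$x[2]
  state_f <- construct_state("folded", Lu - dL, Hu + dH, 0)
  scen <- two_state_scenario(
    state_f, state_u, traps, handle,
    unfolding_rate0_per_s = unfolding_rate0_per_s,
    barrier_position = barrier_position,
    noise_sd_nm = noise_sd_nm,
    sample_rate_hz = sample_rate_hz,
    temperature_K = temperature_K
  )
  scen$midpoint_separation_nm <- sol$x[3]
  scen
}

# cache for calibrated scenarios (calibration is deterministic)
.scenario_cache <- new.env(parent = emptyenv())

#' Wild-type template-complex scenario
#'
#' The default study conditions for the neuronal template complex: a
#' two-state scenario calibrated so that the zero-force unfolding energy is
#' 5.2 kBT, the midpoint mean force 5.1 pN and the midpoint extension change
#' 5.42 nm, with a zero-force unfolding rate of 0.7 1/s (lifetime 1.4 s),
#' Gaussian extension noise of 1.5 nm and 1 kHz sampling. The calibrated
#' contour change is about 31 nm (roughly 86 residues) with a hard-core
#' change of about +2.2 nm.
#'
#' @inheritParams calibrate_two_state_scenario
#' @return A calibrated [two_state_scenario()].
#' @export
wt_template_scenario <- function(unfolding_energy_kbt = 5.2,
                                 equilibrium_force_pN = 5.1,
                                 delta_x_nm = 5.42,
                                 unfolding_rate0_per_s = 0.7,
                                 noise_sd_nm = 1.5,
                                 sample_rate_hz = 1000) {
  key <- paste(unfolding_energy_kbt, equilibrium_force_pN, delta_x_nm,
               unfolding_rate0_per_s, noise_sd_nm, sample_rate_hz, sep = "|")
  if (!is.null(.scenario_cache[[key]])) {
    return(.scenario_cache[[key]])
  }
  scen <- calibrate_two_state_scenario(
    unfolding_energy_kbt = unfolding_energy_kbt,
    equilibrium_force_pN = equilibrium_force_pN,
    delta_x_nm = delta_x_nm,
    unfolding_rate0_per_s = unfolding_rate0_per_s,
    noise_sd_nm = noise_sd_nm,
    sample_rate_hz = sample_rate_hz
  )
  .scenario_cache[[key]] <- scen
  scen
}

#' Generate a benchmark suite of synthetic scenarios
#'
#' Builds one calibrated scenario per row of a mutant parameter table and
#' simulates a constant-separation trajectory set for each, writing
#' trajectories as tab-separated files plus a JSON manifest carrying the
#' complete ground truth. Rows missing the parameters needed for
#' calibration (censored energies, absent rates) are skipped with a
#' warning.
#'
#' @param params Tibble like [template_complex_params()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; trajectory seeds are derived from it.
#' @param forces_pN Mean forces at which to simulate each scenario.
#' @param duration_s Duration of each record.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
generate_benchmark_suite <- function(params, dir, seed,
                                     forces_pN = c(4.5, 5.1, 5.7),
                                     duration_s = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (i in seq_len(nrow(params))) {
    row <- params[i, ]
    ok <- is.finite(row$unfolding_energy_kbt) &&
      is.finite(row$equilibrium_force_pN) &&
      is.finite(row$unfolding_rate_per_s) && !isTRUE(row$censored)
    if (!ok) {
      warning("skipping row '", row$mutation, "': incomplete parameters",
              call. = FALSE)
      next
    }
    scen <- calibrate_two_state_scenario(
      unfolding_energy_kbt = row$unfolding_energy_kbt,
      equilibrium_force_pN = row$equilibrium_force_pN,
      delta_x_nm = 5.42,
      unfolding_rate0_per_s = row$unfolding_rate_per_s
    )
    files <- character(0)
    for (j in seq_along(forces_pN)) {
      D <- separation_for_mean_force(scen, forces_pN[j])
      traj_seed <- (seed + 7919L * i + 101L * j) %% .Machine$integer.max
      traj <- simulate_constant_separation(scen, D, duration_s, traj_seed)
      fn <- sprintf("%s_f%04.1f.tsv", gsub("[^A-Za-z0-9]", "_", row$mutation),
                    forces_pN[j])
      write_trajectory(traj, file.path(dir, fn))
      files <- c(files, fn)
    }
    entries[[row$mutation]] <- list(
      mutation = row$mutation,
      unfolding_energy_kbt = row$unfolding_energy_kbt,
      equilibrium_force_pN = row$equilibrium_force_pN,
      unfolding_rate0_per_s = row$unfolding_rate_per_s,
      folding_rate0_per_s = scen$folding_rate0_per_s,
      midpoint_separation_nm = scen$midpoint_separation_nm,
      forces_pN = forces_pN,
      duration_s = duration_s,
      files = files
    )
  }
  manifest <- list(seed = seed, scenarios = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
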