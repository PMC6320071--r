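#' Optical trap pair
#'
#' Two harmonic optical traps holding the beads of a dumbbell tether. The
#' effective (series) stiffness is k1 k2 / (k1 + k2). Separations are
#' expressed as the relative trap separation, i.e. the constant bead
#' diameters are excluded.
#'
#' @param stiffness_1_pN_nm,stiffness_2_pN_nm Trap stiffnesses in pN/nm (> 0).
#' @return An object of class `trap_pair`.
#' @export
trap_pair <- function(stiffness_1_pN_nm = 0.2, stiffness_2_pN_nm = 0.2) {
  stopifnot(stiffness_1_pN_nm > 0, stiffness_2_pN_nm > 0)
  structure(
    list(k1 = stiffness_1_pN_nm, k2 = stiffness_2_pN_nm),
    class = "trap_pair"
  )
}

#' Effective stiffness of a trap pair
#' @param traps A [trap_pair()].
#' @return Series stiffness k1 k2/(k1 + k2) in pN/nm.
#' @export
trap_stiffness_eff <- function(traps) {
  stopifnot(inherits(traps, "trap_pair"))
  traps$k1 * traps$k2 / (traps$k1 + traps$k2)
}

#' Conformational state of the tethered protein construct
#'
#' Each state of the construct is summarised by the contour length of its
#' disordered (unfolded) polypeptide portion, the force-independent size of
#' its folded portion measured between the two pulling sites (the "hard
#' core"), and its free energy at zero force relative to a declared
#' reference state.
#'
#' @param label State label (e.g. `"folded"`, `"unfolded"`, or a numeric
#'   state id).
#' @param unfolded_contour_nm Contour length of the disordered polypeptide in
#'   nm (>= 0).
#' @param hard_core_nm Hard-core size in nm (>= 0).
#' @param energy_kbt Zero-force free energy V in kBT relative to the
#'   reference state.
#' @return An object of class `construct_state`.
#' @export
construct_state <- function(label, unfolded_contour_nm, hard_core_nm = 0,
                            energy_kbt = 0) {
  stopifnot(unfolded_contour_nm >= 0, hard_core_nm >= 0, is.finite(energy_kbt))
  structure(
    list(
      label = label,
      unfolded_contour_nm = unfolded_contour_nm,
      hard_core_nm = hard_core_nm,
      energy_kbt = energy_kbt
    ),
    class = "construct_state"
  )
}

#' @export
print.construct_state <- function(x, ...) {
  cat(sprintf(
    "<construct_state '%s'> Lp = %g nm, H = %g nm, V = %g kBT\n",
    x$label, x$unfolded_contour_nm, x$hard_core_nm, x$energy_kbt
  ))
  invisible(x)
}

#' Default DNA handle
#'
#' Worm-like chain model of the double-stranded DNA handle: persistence
#' length 40 nm and contour length 0.34 nm/bp (B-DNA rise).
#'
#' @param n_bp Handle length in base pairs.
#' @param persistence_nm Persistence length in nm.
#' @param rise_nm_per_bp Contour length per base pair in nm.
#' @param temperature_K Temperature in kelvin.
#' @return A [wlc_segment()].
#' @export
dna_handle <- function(n_bp = 2260, persistence_nm = 40,
                       rise_nm_per_bp = 0.34, temperature_K = 298) {
  wlc_segment(persistence_nm, n_bp * rise_nm_per_bp, temperature_K)
}

#' Mechanical equilibrium of the dumbbell tether
#'
#' Solves the series force balance of the dumbbell at a fixed relative trap
#' separation D: the two bead displacements (F/k1, F/k2), the DNA handle
#' extension, the unfolded polypeptide extension, and the hard core must add
#' up to D. The tension is uniform along the series at equilibrium; the
#' reported force is the (identical) mean of the two bead forces. If D does
#' not exceed the hard core the tether is slack and the force is zero.
#'
#' @param traps A [trap_pair()].
#' @param state A [construct_state()].
#' @param handle A [wlc_segment()] for the DNA handle.
#' @param separation_nm Relative trap separation D in nm (>= 0).
#' @param temperature_K Temperature in kelvin.
#' @return A tibble with one row per separation: `separation_nm`,
#'   `force_pN`, `extension_nm` (tether extension X), `x_dna_nm`,
#'   `x_protein_nm`, `hard_core_nm`, and `residual_pN` (force-balance
#'   residual of the root solve).
#' @export
#' @examples
#' eq <- dumbbell_equilibrium(
#'   trap_pair(), construct_state("u", 50, 2), dna_handle(), 800
#' )
#' eq$force_pN
dumbbell_equilibrium <- function(traps, state, handle, separation_nm,
                                 temperature_K = 298) {
  stopifnot(
    inherits(traps, "trap_pair"), inherits(state, "construct_state"),
    inherits(handle, "wlc_segment")
  )
  if (any(!is.finite(separation_nm)) || any(separation_nm < 0)) {
    stop("`separation_nm` must be non-negative and finite", call. = FALSE)
  }
  peptide <- wlc_segment(0.6, max(state$unfolded_contour_nm, 0), temperature_K)
  if (state$unfolded_contour_nm > 0) {
    peptide <- wlc_segment(0.6, state$unfolded_contour_nm, temperature_K)
  }
  rows <- lapply(separation_nm, function(D) {
    .solve_dumbbell(traps, state, handle, peptide, D)
  })
  dplyr::bind_rows(rows)
}

.solve_dumbbell <- function(traps, state, handle, peptide, D) {
  H <- state$hard_core_nm
  slack <- function(f) {
    f / traps$k1 + f / traps$k2 +
      wlc_extension(handle, f) +
      (if (peptide$contour_nm > 0) wlc_extension(peptide, f) else 0) +
      H - D
  }
  if (D <= H || slack(0) >= 0) {
    f <- 0
  } else {
    # bracket: residual is strictly increasing in f and negative at 0
    upper <- 1
    while (slack(upper) < 0) upper <- upper * 2
    f <- stats::uniroot(slack, c(0, upper), tol = 1e-12)$root
  }
  x_dna <- wlc_extension(handle, f)
  x_p <- if (peptide$contour_nm > 0) wlc_extension(peptide, f) else 0
  tibble::tibble(
    separation_nm = D,
    force_pN = f,
    extension_nm = if (f == 0) min(D, x_dna + x_p + H) else x_dna + x_p + H,
    x_dna_nm = x_dna,
    x_protein_nm = x_p,
    hard_core_nm = H,
    residual_pN = if (f == 0) 0 else abs(slack(f)) * trap_stiffness_eff(traps)
  )
}

#' Total free energy of the dumbbell system
#'
#' G = F^2/(2 k_traps) + E_DNA + E_p + V, evaluated at the mechanical
#' equilibrium of the given state at the given trap separation: the
#' harmonic energy of the two beads in their traps, the entropic stretching
#' energies of the DNA handle and of the unfolded polypeptide, and the
#' zero-force free energy of the protein state.
#'
#' @inheritParams dumbbell_equilibrium
#' @return Free energy in kBT (vectorised over `separation_nm`).
#' @export
dumbbell_free_energy <- function(traps, state, handle, separation_nm,
                                 temperature_K = 298) {
  eq <- dumbbell_equilibrium(traps, state, handle, separation_nm, temperature_K)
  kT <- kbt(temperature_K)
  peptide_L <- state$unfolded_contour_nm
  e_p <- if (peptide_L > 0) {
    peptide <- wlc_segment(0.6, peptide_L, temperature_K)
    wlc_entropic_energy(peptide, eq$x_protein_nm)
  } else {
    0
  }
  (eq$force_pN^2 / (2 * trap_stiffness_eff(traps)) +
    wlc_entropic_energy(handle, eq$x_dna_nm) + e_p) / kT +
    state$energy_kbt
}

#' Extension and force change between two states at fixed trap separation
#'
#' Predicts the signature of a folding/unfolding transition at constant trap
#' separation: when the protein unfolds (contour released), the tether
#' extension increases while the tension drops, i.e. the two observables
#' change out of phase.
#'
#' @inheritParams dumbbell_equilibrium
#' @param state_a,state_b Two [construct_state()]s solvable at the same
#'   separation.
#' @return A tibble with `delta_x_nm` (X_b - X_a) and `delta_f_pN`
#'   (F_b - F_a).
#' @export
predicted_extension_change <- function(traps, state_a, state_b, handle,
                                       separation_nm, temperature_K = 298) {
  eq_a <- dumbbell_equilibrium(traps, state_a, handle, separation_nm, temperature_K)
  eq_b <- dumbbell_equilibrium(traps, state_b, handle, separation_nm, temperature_K)
  tibble::tibble(
    separation_nm = separation_nm,
    delta_x_nm = eq_b$extension_nm - eq_a$extension_nm,
    delta_f_pN = eq_b$force_pN - eq_a$force_pN
  )
}

#' Trap separation producing a given equilibrium force
#'
#' Inverse of [dumbbell_equilibrium()] in the separation: finds D such that
#' the equilibrium tension of the given state equals `force_pN`.
#'
#' @inheritParams dumbbell_equilibrium
#' @param force_pN Target tension in pN (> 0).
#' @return Separation D in nm.
#' @export
separation_for_force <- function(traps, state, handle, force_pN,
                                 temperature_K = 298) {
  stopifnot(force_pN > 0)
  peptide_L <- state$unfolded_contour_nm
  x_p <- if (peptide_L > 0) {
    wlc_extension(wlc_segment(0.6, peptide_L, temperature_K), force_pN)
  } else {
    0
  }
  force_pN / traps$k1 + force_pN / traps$k2 +
    wlc_extension(handle, force_pN) + x_p + state$hard_core_nm
}
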