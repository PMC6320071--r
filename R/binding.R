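#' Bimolecular on-rate of an intramolecularly tethered ligand
#'
#' When binding and folding are coupled, the observed folding rate of the
#' tethered complex equals the bimolecular on-rate times the effective local
#' concentration of the ligand: k_fold = k_on * c, so
#' k_on = k_fold / c_eff.
#'
#' @param folding_rate_per_s Observed folding rate in 1/s (> 0).
#' @param effective_concentration_M Effective ligand concentration in mol/L
#'   (> 0), e.g. from [effective_concentration()].
#' @return k_on in 1/(M s).
#' @export
intramolecular_kon <- function(folding_rate_per_s, effective_concentration_M) {
  stopifnot(folding_rate_per_s > 0, effective_concentration_M > 0)
  folding_rate_per_s / effective_concentration_M
}

#' Dissociation constant and binding energy from rates
#'
#' K_d = k_off / k_on; the standard-state (1 M) binding free energy is
#' ln(1 M / K_d) in kBT.
#'
#' @param k_off_per_s Dissociation rate in 1/s (> 0).
#' @param k_on_per_M_s Association rate constant in 1/(M s) (> 0).
#' @param standard_state_M Reference concentration; default 1 M.
#' @return A one-row tibble with `kd_M` and `binding_energy_kbt`.
#' @export
#' @examples
#' dissociation_chain(0.7, 3.5e5) # Kd = 2 uM, 13.1 kBT
dissociation_chain <- function(k_off_per_s, k_on_per_M_s,
                               standard_state_M = 1) {
  stopifnot(k_off_per_s > 0, k_on_per_M_s > 0, standard_state_M > 0)
  kd <- k_off_per_s / k_on_per_M_s
  tibble::tibble(
    kd_M = kd,
    binding_energy_kbt = log(standard_state_M / kd)
  )
}

#' Extrapolate a dissociation constant across a free-energy offset
#'
#' A binding that must pay an additional free-energy cost ddG (in kBT)
#' weakens by the corresponding Boltzmann factor: K_d' = K_d exp(ddG).
#'
#' @param kd_M Dissociation constant in M (> 0).
#' @param ddg_kbt Additional free-energy cost in kBT (may be negative).
#' @return Extrapolated dissociation constant in M.
#' @export
#' @examples
#' extrapolate_affinity(2e-6, 4.6) # ~2e-4 M
extrapolate_affinity <- function(kd_M, ddg_kbt) {
  stopifnot(kd_M > 0, is.finite(ddg_kbt))
  kd_M * exp(ddg_kbt)
}

#' Bimolecular rate constant from binding statistics
#'
#' Two estimators for a bimolecular rate constant observed in hold
#' experiments: from the binding probability within a fixed waiting window,
#' k = -ln(1 - P) / (c * t); or from the mean waiting time before binding,
#' k = 1 / (mean_wait * c).
#'
#' @param concentration_M Ligand concentration in M (> 0).
#' @param prob_bind Binding probability per window, in (0, 1).
#' @param window_s Waiting window in s (required with `prob_bind`).
#' @param mean_wait_s Mean waiting time in s (alternative input).
#' @return Rate constant in 1/(M s). A binding probability of exactly 1
#'   makes the probability estimator infinite and raises an error.
#' @export
bimolecular_rate <- function(concentration_M, prob_bind = NULL,
                             window_s = NULL, mean_wait_s = NULL) {
  stopifnot(concentration_M > 0)
  if (!is.null(prob_bind)) {
    stopifnot(!is.null(window_s), window_s > 0, prob_bind > 0)
    if (prob_bind >= 1) {
      stop("binding probability of 1 gives an unbounded rate estimate; ",
           "use the waiting-time form", call. = FALSE)
    }
    return(-log(1 - prob_bind) / (concentration_M * window_s))
  }
  stopifnot(!is.null(mean_wait_s), mean_wait_s > 0)
  1 / (mean_wait_s * concentration_M)
}

#' Relative fusion-rate prediction for a mutant complex
#'
#' Predicted fold-change in the overall fusion rate of a mutant relative to
#' wild type, assuming the templated intermediate is rate-limiting:
#' k_m/k_WT = (r_m/r_WT) exp(G_m - G_WT), where G is the unfolding energy of
#' the intermediate (kBT) and r its downstream binding measure (here the
#' SNAP-25 binding probability, used as a simple ratio). Uncertainty is
#' propagated to first order from the standard errors of the energies.
#'
#' @param g_mutant_kbt,g_wt_kbt Unfolding energies in kBT.
#' @param r_mutant,r_wt Binding measures (> 0).
#' @param se_g_mutant_kbt,se_g_wt_kbt Optional standard errors of the
#'   energies.
#' @return A one-row tibble with `fold_change` and `fold_change_sd`.
#' @export
#' @examples
#' relative_fusion_rate(6.0, 5.2, 0.9, 0.7, 0.3, 0.1) # ~2.9 fold
relative_fusion_rate <- function(g_mutant_kbt, g_wt_kbt, r_mutant, r_wt,
                                 se_g_mutant_kbt = NA_real_,
                                 se_g_wt_kbt = NA_real_) {
  stopifnot(r_mutant > 0, r_wt > 0)
  fc <- (r_mutant / r_wt) * exp(g_mutant_kbt - g_wt_kbt)
  sd <- if (is.finite(se_g_mutant_kbt) || is.finite(se_g_wt_kbt)) {
    fc * sqrt(sum(c(se_g_mutant_kbt, se_g_wt_kbt)^2, na.rm = TRUE))
  } else {
    NA_real_
  }
  tibble::tibble(fold_change = fc, fold_change_sd = sd)
}

#' Fusion-rate predictions for a table of mutants
#'
#' Applies [relative_fusion_rate()] to every row of a mutant parameter
#' table against its wild-type row. Mutants whose unfolding energy is below
#' the detection limit (censored, recorded as `NA`) are reported as
#' abolished rather than given a numeric fold change.
#'
#' @param params A tibble shaped like [template_complex_params()]: columns
#'   `protein`, `mutation`, `unfolding_energy_kbt`, `unfolding_energy_se_kbt`,
#'   `snap25_binding_prob`, and a logical `censored` marking below-detection
#'   energies.
#' @param wt_label Value of `mutation` identifying the wild-type row.
#' @return The input with `fold_change`, `fold_change_sd` and an `abolished`
#'   flag appended.
#' @export
predict_fusion_rates <- function(params, wt_label = "WT") {
  wt <- dplyr::filter(params, .data$mutation == wt_label)
  if (nrow(wt) != 1L) stop("need exactly one wild-type row", call. = FALSE)
  purrr::pmap_dfr(params, function(...) {
    row <- list(...)
    censored <- isTRUE(row$censored) || !is.finite(row$unfolding_energy_kbt) ||
      !is.finite(row$snap25_binding_prob) || row$snap25_binding_prob <= 0
    if (censored) {
      out <- tibble::tibble(fold_change = NA_real_, fold_change_sd = NA_real_,
                            abolished = TRUE)
    } else {
      out <- relative_fusion_rate(
        row$unfolding_energy_kbt, wt$unfolding_energy_kbt,
        row$snap25_binding_prob, wt$snap25_binding_prob,
        row$unfolding_energy_se_kbt, wt$unfolding_energy_se_kbt
      )
      out$abolished <- FALSE
    }
    dplyr::bind_cols(tibble::as_tibble(row[c("protein", "mutation")]), out)
  })
}
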