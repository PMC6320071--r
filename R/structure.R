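#' Residues sequestered by a folding transition
#'
#' Converts a measured transition extension change at force into a
#' contour-length change and a residue count. The folding extension drop at
#' force F satisfies delta_x = z(F) * delta_L - delta_H, where z(F) is the
#' relative worm-like chain extension of the unfolded polypeptide
#' (persistence length 0.6 nm) and delta_H is the signed hard-core change
#' (positive when the folded state's hard core is larger). The residue count
#' is the contour change divided by 0.365 nm per amino acid.
#'
#' @param delta_x_nm Measured extension change in nm (> 0 for a folding
#'   transition).
#' @param force_pN Force at which the change was measured (> 0).
#' @param delta_hard_core_nm Signed hard-core change in nm, folded minus
#'   unfolded; default +3.
#' @param persistence_nm Persistence length of the released polypeptide.
#' @param sd_delta_x_nm Optional standard error of `delta_x_nm`, linearly
#'   propagated to the residue count.
#' @param temperature_K Temperature in kelvin.
#' @return A one-row tibble with `contour_change_nm`, `residues` (real
#'   valued) and `residues_sd`.
#' @export
#' @examples
#' residues_sequestered(5.42, 5.1, delta_hard_core_nm = 3)
residues_sequestered <- function(delta_x_nm, force_pN, delta_hard_core_nm = 3,
                                 persistence_nm = 0.6, sd_delta_x_nm = NULL,
                                 temperature_K = 298) {
  stopifnot(delta_x_nm > 0, force_pN > 0)
  z <- wlc_relative_extension(force_pN, persistence_nm, temperature_K)
  if (z < 0.05) {
    stop("relative extension below 0.05 at this force; the contour change ",
         "is ill-conditioned - use higher-force measurements", call. = FALSE)
  }
  dL <- (delta_x_nm + delta_hard_core_nm) / z
  res <- residues_from_contour(dL, round_to_integer = FALSE)
  res_sd <- if (is.null(sd_delta_x_nm)) {
    NA_real_
  } else {
    residues_from_contour(sd_delta_x_nm / z, round_to_integer = FALSE)
  }
  tibble::tibble(
    contour_change_nm = dL,
    residues = res,
    residues_sd = res_sd
  )
}

#' Construct definition for residue bookkeeping
#'
#' Describes the polypeptide span between the two pulling sites of a
#' tethered construct and the per-state structure: how many residues of the
#' span are sequestered (folded) in each state and the state's hard-core
#' size. The crosslink that closes the loop between the two SNARE motifs is
#' recorded for validation.
#'
#' @param span_residues Total number of residues in the disordered span
#'   between the pulling sites when fully unfolded (> 0).
#' @param states A tibble (or data.frame) with columns `label`,
#'   `sequestered_residues`, `hard_core_nm`.
#' @param crosslink_position Optional residue index of the crosslink within
#'   the span, validated to lie inside the sequence.
#' @return An object of class `construct_definition`.
#' @export
construct_definition <- function(span_residues, states,
                                 crosslink_position = NULL) {
  if (span_residues <= 0) stop("construct has zero length", call. = FALSE)
  states <- tibble::as_tibble(states)
  stopifnot(all(c("label", "sequestered_residues", "hard_core_nm") %in%
                  names(states)))
  if (any(states$sequestered_residues < 0) ||
      any(states$sequestered_residues > span_residues)) {
    stop("sequestered residues must lie within the construct span",
         call. = FALSE)
  }
  if (!is.null(crosslink_position) &&
      (crosslink_position < 1 || crosslink_position > span_residues)) {
    stop("crosslink position lies outside the sequence", call. = FALSE)
  }
  structure(
    list(
      span_residues = span_residues,
      states = states,
      crosslink_position = crosslink_position
    ),
    class = "construct_definition"
  )
}

#' Per-state unfolded contour lengths of a construct
#'
#' Residue bookkeeping: for each modelled state, the unfolded contour length
#' is the unsequestered part of the span times 0.365 nm per amino acid.
#'
#' @param construct A [construct_definition()].
#' @return A tibble with `label`, `unfolded_residues`,
#'   `unfolded_contour_nm`, `hard_core_nm`.
#' @export
state_contour_table <- function(construct) {
  stopifnot(inherits(construct, "construct_definition"))
  st <- construct$states
  tibble::tibble(
    label = st$label,
    unfolded_residues = construct$span_residues - st$sequestered_residues,
    unfolded_contour_nm = contour_from_residues(
      construct$span_residues - st$sequestered_residues
    ),
    hard_core_nm = st$hard_core_nm
  )
}
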