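#' Thermal energy in pN nm
#'
#' Boltzmann constant times absolute temperature, in the piconewton-nanometre
#' units used throughout the package. At the default 298 K this is
#' approximately 4.114 pN nm.
#'
#' @param temperature_K Absolute temperature in kelvin.
#' @return Thermal energy kBT in pN nm.
#' @export
#' @examples
#' kbt() # 4.114 pN nm
kbt <- function(temperature_K = 298) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  0.0138064852 * temperature_K
}

# contour length per amino acid, nm
.CONTOUR_PER_AA <- 0.365

# kcal/mol per kBT at 298 K
.KCAL_PER_KBT <- 0.593

# 1 nm^-3 expressed as mol/L: 1e24 nm^3/L / Avogadro
.AVOGADRO <- 6.02214076e23
.NM3_TO_MOLAR <- 1e24 / .AVOGADRO

#' Convert an energy between kBT and kcal/mol
#'
#' Uses 0.593 kcal/mol per kBT at 298 K.
#'
#' @param energy_kbt Energy in units of kBT.
#' @return Energy in kcal/mol.
#' @export
kbt_to_kcal <- function(energy_kbt) energy_kbt * .KCAL_PER_KBT

#' Contour length of a polypeptide from its residue count
#'
#' The contour length per amino acid is 0.365 nm.
#'
#' @param n_residues Number of amino acids (may be fractional for
#'   uncertainty-propagated counts).
#' @return Contour length in nm.
#' @export
#' @examples
#' contour_from_residues(54) # 19.7 nm
contour_from_residues <- function(n_residues) {
  if (any(!is.finite(n_residues)) || any(n_residues < 0)) {
    stop("`n_residues` must be non-negative and finite", call. = FALSE)
  }
  n_residues * .CONTOUR_PER_AA
}

#' @rdname contour_from_residues
#' @param contour_nm Contour length in nm.
#' @param round_to_integer Round the residue count to the nearest integer?
#' @export
residues_from_contour <- function(contour_nm, round_to_integer = TRUE) {
  if (any(!is.finite(contour_nm)) || any(contour_nm < 0)) {
    stop("`contour_nm` must be non-negative and finite", call. = FALSE)
  }
  n <- contour_nm / .CONTOUR_PER_AA
  if (round_to_integer) round(n) else n
}
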