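#' Tethered ligand model
#'
#' Describes a ligand held near its binding pocket by a disordered
#' polypeptide linker: the linker contour length, the spatial distance
#' between the tethering point and the pocket, and the linker persistence
#' length. Used to compute the effective local concentration of the ligand
#' from the Gaussian-chain end-to-end distribution.
#'
#' @param linker_contour_nm Contour length L of the linker in nm (> 0).
#' @param pocket_distance_nm Distance R from the tethering point to the
#'   binding pocket in nm (> 0). May exceed the contour length, in which case
#'   the concentration is negligibly small but still defined.
#' @param persistence_nm Persistence length p of the linker in nm; default
#'   0.6 nm for an unfolded polypeptide.
#' @return An object of class `tethered_ligand`.
#' @export
#' @examples
#' # 54-residue linker, pocket 6.34 nm away
#' tl <- tethered_ligand(contour_from_residues(54), 6.34)
#' effective_concentration(tl) # ~3.7e-4 M
tethered_ligand <- function(linker_contour_nm, pocket_distance_nm,
                            persistence_nm = 0.6) {
  stopifnot(
    is.numeric(linker_contour_nm), linker_contour_nm > 0,
    is.numeric(pocket_distance_nm), pocket_distance_nm > 0,
    is.numeric(persistence_nm), persistence_nm > 0
  )
  structure(
    list(
      linker_contour_nm = linker_contour_nm,
      pocket_distance_nm = pocket_distance_nm,
      persistence_nm = persistence_nm
    ),
    class = "tethered_ligand"
  )
}

#' @export
print.tethered_ligand <- function(x, ...) {
  cat(sprintf(
    "<tethered_ligand> L = %g nm, R = %g nm, p = %g nm  (c = %.3g M)\n",
    x$linker_contour_nm, x$pocket_distance_nm, x$persistence_nm,
    effective_concentration(x)
  ))
  invisible(x)
}

#' Effective concentration of a tethered ligand
#'
#' Gaussian-chain end-to-end density evaluated at the pocket distance:
#' c = (1/NA) (3 / (4 pi p L))^(3/2) exp(-3 R^2 / (4 p L)),
#' converted from nm^-3 to mol/L. Strictly decreasing in R, maximised at
#' R = 0.
#'
#' @param model A [tethered_ligand()].
#' @return Effective molar concentration in mol/L.
#' @export
effective_concentration <- function(model) {
  stopifnot(inherits(model, "tethered_ligand"))
  L <- model$linker_contour_nm
  R <- model$pocket_distance_nm
  p <- model$persistence_nm
  density_nm3 <- (3 / (4 * pi * p * L))^1.5 * exp(-3 * R^2 / (4 * p * L))
  density_nm3 * .NM3_TO_MOLAR
}
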