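#' Construct a trajectory tibble
#'
#' A trajectory is a tibble with uniformly sampled columns `time_s`,
#' `extension_nm` and `force_pN`, recorded at a constant relative trap
#' separation (stored in the `trap_separation_nm` attribute along with
#' free-form `metadata`).
#'
#' @param time_s Time stamps in seconds (uniform spacing, length >= 2).
#' @param extension_nm Tether extension in nm.
#' @param force_pN Tether tension in pN.
#' @param trap_separation_nm Constant relative trap separation in nm
#'   (optional).
#' @param metadata Named list of free-form metadata (molecule id, construct,
#'   buffer, ...).
#' @return A tibble of class `trajectory`.
#' @export
trajectory <- function(time_s, extension_nm, force_pN = NULL,
                       trap_separation_nm = NA_real_, metadata = list()) {
  n <- length(time_s)
  if (n < 2L) stop("a trajectory needs at least 2 samples", call. = FALSE)
  if (is.null(force_pN)) force_pN <- rep(NA_real_, n)
  stopifnot(length(extension_nm) == n, length(force_pN) == n)
  if (!all(is.finite(time_s)) || !all(is.finite(extension_nm))) {
    stop("time and extension must be finite", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time base must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("time base must be uniform", call. = FALSE)
  }
  out <- tibble::tibble(
    time_s = as.numeric(time_s),
    extension_nm = as.numeric(extension_nm),
    force_pN = as.numeric(force_pN)
  )
  attr(out, "trap_separation_nm") <- trap_separation_nm
  attr(out, "metadata") <- metadata
  class(out) <- c("trajectory", class(out))
  out
}

#' Sampling rate of a trajectory in Hz
#' @param traj A [trajectory()].
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(traj) {
  1 / stats::median(diff(traj$time_s))
}
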