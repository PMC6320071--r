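#' Trap stiffness from the power spectrum of bead fluctuations
#'
#' Fits the one-sided power spectral density of a trapped bead's position
#' fluctuations with a Lorentzian, S(f) = A / (fc^2 + f^2). For an
#' overdamped bead in a harmonic trap the corner frequency is
#' fc = k / (2 pi gamma), so the stiffness is recovered as
#' k = 2 pi gamma fc, with gamma the bead drag coefficient.
#'
#' @param position_nm Stationary bead position series in nm.
#' @param rate_hz Sampling rate in Hz (must be well above the corner
#'   frequency).
#' @param drag_pN_s_nm Bead drag coefficient gamma in pN s/nm.
#' @param n_bins Number of logarithmic frequency bins used to condense the
#'   periodogram before fitting.
#' @return A one-row tibble with `stiffness_pN_nm`, `corner_frequency_hz`
#'   and the Lorentzian plateau amplitude.
#' @export
calibrate_trap_stiffness <- function(position_nm, rate_hz, drag_pN_s_nm,
                                     n_bins = 60L) {
  stopifnot(length(position_nm) > 256L, rate_hz > 0, drag_pN_s_nm > 0)
  x <- position_nm - mean(position_nm)
  n <- length(x)
  xf <- stats::fft(x)
  half <- seq(2L, floor(n / 2))
  freq <- (half - 1L) * rate_hz / n
  psd <- 2 * Mod(xf[half])^2 / (n * rate_hz) # one-sided, nm^2/Hz

  # condense onto log-spaced bins (periodogram ordinates are exponentially
  # distributed; bin means tame the noise), then least-squares fit the
  # aliased Lorentzian on the log scale, weighted by bin occupancy. For a
  # Lorentzian process observed at discrete times the sampled spectrum is
  # S(f) = A / (1 - 2 rho cos(2 pi f dt) + rho^2) with rho = exp(-2 pi fc dt),
  # which reduces to the plain Lorentzian well below the Nyquist frequency.
  dt <- 1 / rate_hz
  bins <- exp(seq(log(min(freq)), log(max(freq)), length.out = n_bins + 1L))
  grp <- cut(freq, bins, include.lowest = TRUE)
  fbin <- as.numeric(tapply(freq, grp, mean))
  pbin <- as.numeric(tapply(psd, grp, mean))
  m <- as.numeric(tapply(psd, grp, length))
  keep <- is.finite(fbin) & is.finite(pbin) & pbin > 0
  fbin <- fbin[keep]
  pbin <- pbin[keep]
  m <- m[keep]
  plateau <- stats::median(pbin[seq_len(max(3L, length(pbin) %/% 10))])
  below <- which(pbin < plateau / 2)
  fc0 <- if (length(below) > 0L) fbin[below[1]] else stats::median(fbin)
  obj <- function(par) {
    rho <- exp(-2 * pi * abs(par[2]) * dt)
    sum(m * (log(pbin) - par[1] +
               log(1 - 2 * rho * cos(2 * pi * fbin * dt) + rho^2))^2)
  }
  o <- stats::optim(
    c(log(plateau * (1 - exp(-2 * pi * fc0 * dt))^2), fc0), obj,
    control = list(reltol = 1e-14, maxit = 5000)
  )
  if (o$convergence != 0) {
    stop("Lorentzian fit did not converge; check that the series is a ",
         "stationary trapped-bead record", call. = FALSE)
  }
  fc <- abs(o$par[2])
  if (fc > 0.45 * rate_hz / 2 || fc < freq[1]) {
    stop("fitted corner frequency lies outside the resolvable band; ",
         "the record looks like unconfined or white noise", call. = FALSE)
  }
  rho <- exp(-2 * pi * fc * dt)
  tibble::tibble(
    stiffness_pN_nm = 2 * pi * drag_pN_s_nm * fc,
    corner_frequency_hz = fc,
    plateau_nm2_hz = exp(o$par[1]) / (1 - rho)^2
  )
}
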