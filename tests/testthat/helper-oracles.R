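# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# half-maximum threshold-crossing segmentation (oracle for the HMM on
# noiseless traces): state 2 above the midpoint of the observed range
threshold_idealize <- function(x) {
  thr <- (min(x) + max(x)) / 2
  ifelse(x > thr, 2L, 1L)
}

# trapezoidal quadrature of the Marko-Siggia force (oracle for the
# closed-form entropic energy)
wlc_energy_quadrature <- function(P, L, x, temperature_K = 298, n = 20000L) {
  grid <- seq(0, x, length.out = n)
  z <- grid / L
  kT <- 0.0138064852 * temperature_K
  f <- kT / P * (0.25 / (1 - z)^2 + z - 0.25)
  sum((f[-1] + f[-n]) / 2) * (x / (n - 1))
}

# bisection inverse of the dimensionless Marko-Siggia relation (oracle for
# the package's Newton inverse)
wlc_z_bisect <- function(f_dimensionless) {
  lo <- 0
  hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    val <- 0.25 / (1 - mid)^2 + mid - 0.25
    if (val < f_dimensionless) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Monte-Carlo estimate of the Gaussian-chain end-to-end density at radius R
# (nm^-3); per-coordinate variance 2 p L / 3
gaussian_chain_density_mc <- function(L, R, p, n = 1e7, shell_nm = 0.4,
                                      seed = 42) {
  withr::with_seed(seed, {
    sd1 <- sqrt(2 * p * L / 3)
    r2 <- rnorm(n, 0, sd1)^2 + rnorm(n, 0, sd1)^2 + rnorm(n, 0, sd1)^2
    r <- sqrt(r2)
    inside <- mean(r >= R - shell_nm / 2 & r < R + shell_nm / 2)
    shell_vol <- 4 / 3 * pi * ((R + shell_nm / 2)^3 - (R - shell_nm / 2)^3)
    inside / shell_vol
  })
}

# direct two-state Markov trajectory generator, independent of the package
# simulator (oracle for the HMM rate recovery)
make_two_state_trace <- function(k12, k21, x1 = 0, x2 = 5, noise_sd = 1.5,
                                 rate_hz = 1000, duration_s = 100, seed = 1) {
  withr::with_seed(seed, {
    t_now <- 0
    cur <- 1L
    jumps <- numeric(0)
    states <- cur
    while (t_now < duration_s) {
      k <- if (cur == 1L) k12 else k21
      t_now <- t_now + rexp(1, k)
      if (t_now >= duration_s) break
      cur <- 3L - cur
      jumps <- c(jumps, t_now)
      states <- c(states, cur)
    }
    n <- floor(duration_s * rate_hz)
    ts <- (seq_len(n) - 0.5) / rate_hz
    st <- states[findInterval(ts, jumps) + 1L]
    x <- ifelse(st == 1L, x1, x2) + rnorm(n, 0, noise_sd)
    list(
      traj = trajectory(ts, x, trap_separation_nm = NA_real_),
      states = st
    )
  })
}

# WT study-condition scenario, shared across tests (calibration is cached
# inside the package)
wt_scenario <- function() wt_template_scenario()
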