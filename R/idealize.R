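#' Two-state hidden-Markov idealization of an extension trajectory
#'
#' Fits a two-state hidden Markov model with Gaussian emissions and
#' first-order Markov transitions to the extension channel by
#' expectation-maximisation, then decodes the most probable state path with
#' the Viterbi algorithm. The higher-extension state is labelled "unfolded"
#' (state 2) because unfolding lengthens the tether. Initialisation splits
#' the samples at the extension median, so the fit is deterministic; the
#' `seed` argument is accepted for interface stability and to seed any
#' downstream stochastic consumers.
#'
#' Degenerate records are flagged rather than raised as errors: if one state
#' occupies more than 99.5% of the samples, or the fitted emission means are
#' closer than half the pooled emission standard deviation, the result
#' carries `no_transition = TRUE`.
#'
#' @param traj A [trajectory()].
#' @param seed Integer seed (kept for reproducibility bookkeeping).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param filter_window Optional mean-filter window in samples: the
#'   trajectory is block-averaged (decimated) by this factor before fitting.
#'   `NULL` (default) fits the raw samples.
#' @return An object of class `idealized_trace`: a list with the decoded
#'   `state` path (1 = folded, 2 = unfolded), per-state emission `means_nm`
#'   and `sds_nm`, the fitted `transition_matrix` (per-sample probabilities),
#'   observed `transition_counts`, a `dwells` tibble (state, start time,
#'   duration, censoring flag), the filtered trajectory actually fitted,
#'   `loglik`, and the `no_transition` flag.
#' @export
idealize_two_state <- function(traj, seed = 1L, max_iter = 300L, tol = 1e-8,
                               filter_window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.null(filter_window) && filter_window > 1L) {
    traj <- .block_average(traj, as.integer(filter_window))
  }
  x <- traj$extension_nm
  n <- length(x)
  dt <- 1 / sampling_rate(traj)

  # deterministic initialisation: split at the median
  med <- stats::median(x)
  lo <- x[x <= med]
  hi <- x[x > med]
  if (length(hi) == 0L) hi <- max(x)
  mu <- c(mean(lo), mean(hi))
  s0 <- stats::sd(x) / 2
  sig <- rep(max(s0, 1e-8), 2)
  trans <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  init <- c(0.5, 0.5)

  loglik_old <- -Inf
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    fb <- .hmm_forward_backward(x, mu, sig, init, trans)
    loglik <- fb$loglik
    gam <- fb$gamma
    xi <- fb$xi
    w <- colSums(gam)
    mu_new <- c(sum(gam[, 1] * x), sum(gam[, 2] * x)) / w
    sig_new <- sqrt(c(
      sum(gam[, 1] * (x - mu_new[1])^2),
      sum(gam[, 2] * (x - mu_new[2])^2)
    ) / w)
    floor_sd <- max(1e-6 * (abs(diff(mu_new)) + 1e-9), 1e-9)
    sig <- pmax(sig_new, floor_sd)
    mu <- mu_new
    trans <- xi / pmax(rowSums(xi), 1e-300)
    trans <- pmax(trans, 1e-12)
    trans <- trans / rowSums(trans)
    init <- pmax(gam[1, ], 1e-12)
    init <- init / sum(init)
    if (is.finite(loglik_old) &&
        abs(loglik - loglik_old) < tol * (abs(loglik) + 1)) {
      break
    }
    loglik_old <- loglik
  }

  # order states so state 2 is the higher-extension (unfolded) state
  if (mu[1] > mu[2]) {
    mu <- rev(mu)
    sig <- rev(sig)
    init <- rev(init)
    trans <- trans[2:1, 2:1]
  }
  path <- .hmm_viterbi(x, mu, sig, init, trans)

  occ2 <- mean(path == 2L)
  no_transition <- occ2 > 0.995 || occ2 < 0.005 ||
    abs(diff(mu)) < 0.5 * mean(sig)

  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dwells <- tibble::tibble(
    state = runs$values,
    start_index = starts,
    start_time_s = traj$time_s[starts],
    duration_s = runs$lengths * dt,
    censored = seq_along(runs$values) %in% c(1L, length(runs$values))
  )
  counts <- matrix(0L, 2, 2)
  if (n > 1L) {
    from <- path[-n]
    to <- path[-1L]
    for (i in 1:2) for (j in 1:2) counts[i, j] <- sum(from == i & to == j)
  }

  structure(
    list(
      state = path,
      means_nm = mu,
      sds_nm = sig,
      transition_matrix = trans,
      transition_counts = counts,
      dwells = dwells,
      trajectory = traj,
      loglik = loglik,
      n_iter = iter,
      no_transition = no_transition
    ),
    class = "idealized_trace"
  )
}

.block_average <- function(traj, w) {
  n <- nrow(traj)
  nb <- n %/% w
  idx <- rep(seq_len(nb), each = w)
  keep <- seq_len(nb * w)
  trajectory(
    time_s = tapply(traj$time_s[keep], idx, mean),
    extension_nm = tapply(traj$extension_nm[keep], idx, mean),
    force_pN = if (all(is.na(traj$force_pN))) NULL else
      as.numeric(tapply(traj$force_pN[keep], idx, mean)),
    trap_separation_nm = attr(traj, "trap_separation_nm"),
    metadata = attr(traj, "metadata")
  )
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf(
    "<idealized_trace> %d samples, means %.2f / %.2f nm, %d dwells%s\n",
    length(x$state), x$means_nm[1], x$means_nm[2], nrow(x$dwells),
    if (x$no_transition) " [no transition detected]" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.idealized_trace <- function(x, ...) x$dwells

#' @export
glance.idealized_trace <- function(x, ...) {
  tibble::tibble(
    mean_folded_nm = x$means_nm[1],
    mean_unfolded_nm = x$means_nm[2],
    sd_folded_nm = x$sds_nm[1],
    sd_unfolded_nm = x$sds_nm[2],
    n_dwells = nrow(x$dwells),
    loglik = x$loglik,
    no_transition = x$no_transition
  )
}

#' Dwell and transition statistics of an idealized trajectory
#'
#' Summarises an [idealize_two_state()] result: time-weighted unfolded-state
#' occupancy, folding and unfolding rates from mean dwell durations
#' (censored first and last dwells excluded), the extension change as the
#' difference of the emission means, and the per-state and record mean
#' forces. The record mean force is the mean of the two per-state average
#' forces. Rates are also reported from the fitted HMM transition matrix
#' (per-sample probability times sampling rate) as a cross-check.
#'
#' @param idealized An `idealized_trace`.
#' @param traj Optionally, the original trajectory (defaults to the one
#'   stored in `idealized`).
#' @return A one-row tibble with occupancy, rates (1/s; `NA` when a state
#'   was never exited uncensored), `delta_x_nm`, per-state mean forces, the
#'   trap separation, and dwell/transition counts.
#' @export
dwell_statistics <- function(idealized, traj = idealized$trajectory) {
  stopifnot(inherits(idealized, "idealized_trace"))
  path <- idealized$state
  dw <- idealized$dwells
  occ_unfolded <- mean(path == 2L)

  mean_dwell <- function(s) {
    d <- dw$duration_s[dw$state == s & !dw$censored]
    if (length(d) == 0L) NA_real_ else mean(d)
  }
  k_unfolding <- 1 / mean_dwell(1L) # rate out of the folded state
  k_folding <- 1 / mean_dwell(2L) # rate out of the unfolded state

  rate <- sampling_rate(traj)
  a <- idealized$transition_matrix
  force <- traj$force_pN
  f_folded <- if (all(is.na(force))) NA_real_ else mean(force[path == 1L])
  f_unfolded <- if (all(is.na(force))) NA_real_ else mean(force[path == 2L])

  tibble::tibble(
    trap_separation_nm = attr(traj, "trap_separation_nm"),
    occupancy_unfolded = occ_unfolded,
    folding_rate_per_s = k_folding,
    unfolding_rate_per_s = k_unfolding,
    folding_rate_hmm_per_s = a[2, 1] * rate,
    unfolding_rate_hmm_per_s = a[1, 2] * rate,
    delta_x_nm = diff(idealized$means_nm),
    force_folded_pN = f_folded,
    force_unfolded_pN = f_unfolded,
    force_mean_pN = (f_folded + f_unfolded) / 2,
    n_dwells = nrow(dw),
    n_transitions = sum(idealized$transition_counts[1, 2],
                        idealized$transition_counts[2, 1]),
    no_transition = idealized$no_transition
  )
}

#' Equilibrium (midpoint) force from a force scan
#'
#' Interpolates unfolded-state occupancy against the record mean force to
#' the point of equal population (occupancy 0.5) and returns the mean of
#' the two per-state average forces interpolated at that point.
#'
#' @param stats A tibble of [dwell_statistics()] rows spanning occupancies
#'   both below and above 0.5.
#' @return A one-row tibble with `equilibrium_force_pN` and the per-state
#'   forces at the midpoint.
#' @export
equilibrium_force <- function(stats) {
  stopifnot(all(c(
    "occupancy_unfolded", "force_folded_pN", "force_unfolded_pN"
  ) %in% names(stats)))
  occ <- stats$occupancy_unfolded
  if (min(occ) > 0.5 || max(occ) < 0.5) {
    stop(
      "occupancies do not bracket 0.5; record trajectories over a wider ",
      "force (trap separation) range",
      call. = FALSE
    )
  }
  ord <- order(occ)
  f_f <- stats::approx(occ[ord], stats$force_folded_pN[ord], xout = 0.5,
                       ties = mean)$y
  f_u <- stats::approx(occ[ord], stats$force_unfolded_pN[ord], xout = 0.5,
                       ties = mean)$y
  tibble::tibble(
    equilibrium_force_pN = (f_f + f_u) / 2,
    force_folded_pN = f_f,
    force_unfolded_pN = f_u
  )
}
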