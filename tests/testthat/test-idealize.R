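test_that("noiseless square wave is segmented exactly, matching the threshold oracle", {
  x <- rep(rep(c(0, 5), 5), each = 500) # 10 dwells of 0.5 s at 1 kHz
  tr <- trajectory(seq_along(x) / 1000, x)
  id <- idealize_two_state(tr)
  expect_identical(id$state, threshold_idealize(x))
  expect_identical(nrow(id$dwells), 10L)
  expect_equal(sort(unique(id$dwells$duration_s)), 0.5)
  expect_equal(id$means_nm, c(0, 5), tolerance = 1e-9)
  expect_false(id$no_transition)
})

test_that("rates and extension change are recovered from a known Markov trace", {
  sim <- make_two_state_trace(
    k12 = 1, k21 = 1, x1 = 0, x2 = 5, noise_sd = 1.5,
    rate_hz = 1000, duration_s = 200, seed = 21
  )
  id <- idealize_two_state(sim$traj)
  st <- dwell_statistics(id)
  expect_equal(st$unfolding_rate_per_s, 1, tolerance = 0.15)
  expect_equal(st$folding_rate_per_s, 1, tolerance = 0.15)
  expect_equal(st$delta_x_nm, 5, tolerance = 0.05)
  expect_equal(st$occupancy_unfolded, 0.5, tolerance = 0.1)
  # dwell-mean and transition-matrix rate estimators agree
  expect_equal(st$folding_rate_hmm_per_s, st$folding_rate_per_s,
               tolerance = 0.1)
  expect_equal(st$unfolding_rate_hmm_per_s, st$unfolding_rate_per_s,
               tolerance = 0.1)
})

test_that("pure-noise records are flagged, not fitted", {
  withr::with_seed(5, {
    tr <- trajectory(seq_len(20000) / 1000, rnorm(20000, 100, 1.5))
  })
  id <- idealize_two_state(tr)
  expect_true(id$no_transition)
  st <- dwell_statistics(id)
  expect_true(st$no_transition)
  expect_true(is.finite(st$occupancy_unfolded))
})

test_that("idealization is offset-invariant and sign-equivariant", {
  sim <- make_two_state_trace(2, 2, 0, 5, 1.2, 1000, 50, seed = 9)
  base <- idealize_two_state(sim$traj)
  shifted <- trajectory(sim$traj$time_s, sim$traj$extension_nm + 250)
  id_sh <- idealize_two_state(shifted)
  expect_identical(id_sh$state, base$state)
  expect_equal(id_sh$means_nm, base$means_nm + 250, tolerance = 1e-6)
  flipped <- trajectory(sim$traj$time_s, -sim$traj$extension_nm)
  id_fl <- idealize_two_state(flipped)
  expect_identical(id_fl$state, 3L - base$state)
  expect_equal(id_fl$means_nm, rev(-base$means_nm), tolerance = 1e-6)
})

test_that("deterministic dwell pattern yields exact statistics", {
  # 10 alternating dwells of exactly 1 s
  x <- rep(rep(c(0, 6), 5), each = 1000)
  tr <- trajectory(seq_along(x) / 1000, x,
                   force_pN = rep(c(5.4, 4.8), 5)[rep(1:10, each = 1000)])
  st <- dwell_statistics(idealize_two_state(tr))
  expect_equal(st$occupancy_unfolded, 0.5)
  expect_equal(st$folding_rate_per_s, 1, tolerance = 1e-9)
  expect_equal(st$unfolding_rate_per_s, 1, tolerance = 1e-9)
  # the record mean force is the mean of the two per-state averages
  expect_equal(st$force_mean_pN, (5.4 + 4.8) / 2, tolerance = 1e-9)
})

test_that("midpoint force interpolates occupancy to equal population", {
  stats <- tibble::tibble(
    occupancy_unfolded = c(0.4, 0.6),
    force_folded_pN = c(5.1, 5.3),
    force_unfolded_pN = c(4.7, 4.9),
    force_mean_pN = c(4.9, 5.1)
  )
  eq <- equilibrium_force(stats)
  # hand interpolation: halfway between the two records
  expect_equal(eq$force_folded_pN, 5.2, tolerance = 1e-12)
  expect_equal(eq$force_unfolded_pN, 4.8, tolerance = 1e-12)
  expect_equal(eq$equilibrium_force_pN, 5.0, tolerance = 1e-12)
  # occupancies that do not bracket 0.5 are an error
  low <- dplyr::mutate(stats, occupancy_unfolded = c(0.1, 0.3))
  expect_error(equilibrium_force(low), "bracket")
})

test_that("recovered dwell durations are exponential with the recovered rate", {
  passes <- 0L
  n_seeds <- 5L
  scen <- wt_scenario()
  for (s in seq_len(n_seeds)) {
    tr <- simulate_constant_separation(scen, scen$midpoint_separation_nm,
                                       60, seed = 300 + s)
    id <- idealize_two_state(tr)
    st <- dwell_statistics(id)
    d_f <- id$dwells$duration_s[id$dwells$state == 1 & !id$dwells$censored]
    d_u <- id$dwells$duration_s[id$dwells$state == 2 & !id$dwells$censored]
    p1 <- suppressWarnings(
      stats::ks.test(d_f, "pexp", st$unfolding_rate_per_s)$p.value
    )
    p2 <- suppressWarnings(
      stats::ks.test(d_u, "pexp", st$folding_rate_per_s)$p.value
    )
    if (p1 > 0.01 && p2 > 0.01) passes <- passes + 1L
  }
  expect_gte(passes, n_seeds - 1L)
})
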