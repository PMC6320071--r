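scen <- wt_scenario()

test_that("simulation is reproducible given the seed", {
  a <- simulate_constant_separation(scen, scen$midpoint_separation_nm, 5, seed = 17)
  b <- simulate_constant_separation(scen, scen$midpoint_separation_nm, 5, seed = 17)
  expect_identical(a$extension_nm, b$extension_nm)
  expect_identical(a$force_pN, b$force_pN)
  c <- simulate_constant_separation(scen, scen$midpoint_separation_nm, 5, seed = 18)
  expect_false(identical(a$extension_nm, c$extension_nm))
})

test_that("occupancy follows the Boltzmann distribution of the dumbbell energy", {
  # find a separation where the unfolded state costs ~2 kBT
  D2 <- stats::uniroot(
    function(D) scenario_rates(scen, D)$delta_g_kbt - 2,
    scen$midpoint_separation_nm + c(-20, 0)
  )$root
  tr <- simulate_constant_separation(scen, D2, 150, seed = 101)
  id <- idealize_two_state(tr)
  occ <- mean(id$state == 2L)
  expect_equal(occ, 1 / (1 + exp(2)), tolerance = 0.25)
})

test_that("empirical kinetics satisfy detailed balance against the model energy", {
  for (dG_target in c(-1, 0, 1)) {
    D <- stats::uniroot(
      function(D) scenario_rates(scen, D)$delta_g_kbt - dG_target,
      scen$midpoint_separation_nm + c(-25, 25)
    )$root
    tr <- simulate_constant_separation(scen, D, 80, seed = 200 + dG_target)
    st <- dwell_statistics(idealize_two_state(tr))
    # ln(k_f/k_u) should equal delta G (unfolded minus folded)
    n_f <- sum(st$n_dwells) / 2
    se <- sqrt(2 / n_f) # log-rate-ratio standard error from dwell counts
    expect_lt(
      abs(log(st$folding_rate_per_s / st$unfolding_rate_per_s) - dG_target),
      3 * se + 0.15
    )
  }
})

test_that("trajectory force channel is slaved to extension through the traps", {
  tr <- simulate_constant_separation(scen, scen$midpoint_separation_nm, 5,
                                     seed = 3)
  k_eff <- trap_stiffness_eff(scen$traps)
  expect_equal(
    tr$force_pN,
    k_eff * (scen$midpoint_separation_nm - tr$extension_nm),
    tolerance = 1e-12
  )
  # out-of-phase: force drops when extension jumps up
  expect_lt(stats::cor(tr$force_pN, tr$extension_nm), -0.99)
})

test_that("constant-speed pulls flicker near the midpoint and agree on it", {
  D_lo <- scen$midpoint_separation_nm - 12
  D_hi <- scen$midpoint_separation_nm + 12
  pulls <- lapply(1:3, function(s) {
    simulate_pull(scen, D_lo, D_hi, speed_nm_s = 4, seed = 400 + s)
  })
  pooled <- dplyr::bind_rows(pulls)
  # transitions are present in the pulled window (flickering signature)
  n_trans <- sum(abs(diff(pooled$state)) > 0)
  expect_gt(n_trans, 10)
  # unfolding events drop the force
  jumps <- which(diff(pooled$state) == 1L)
  jumps <- jumps[jumps > 1 & jumps < nrow(pooled) - 1]
  # logistic midpoint of state vs separation matches the constant-separation one
  fit <- stats::glm(I(state == 2L) ~ separation_nm, data = pooled,
                    family = stats::binomial())
  D_half <- -stats::coef(fit)[1] / stats::coef(fit)[2]
  r <- scenario_rates(scen, as.numeric(D_half))
  f_half <- (r$force_folded_pN + r$force_unfolded_pN) / 2
  expect_equal(f_half, 5.1, tolerance = 0.02) # ~0.1 pN absolute
})

test_that("rip forces shift upward with pulling speed for rare unfolding", {
  # a stable construct pulled out of equilibrium rips stochastically;
  # faster ramps reach higher forces before the first rip
  slow_scen <- calibrate_two_state_scenario(
    unfolding_energy_kbt = 9, equilibrium_force_pN = 8, delta_x_nm = 8,
    unfolding_rate0_per_s = 0.05, noise_sd_nm = 1.0
  )
  first_rip_force <- function(speed, seed) {
    D0 <- slow_scen$midpoint_separation_nm
    p <- simulate_pull(slow_scen, D0 - 30, D0 + 25, speed_nm_s = speed,
                       seed = seed)
    i <- which(p$state == 2L)[1]
    if (is.na(i)) NA_real_ else p$force_pN[i]
  }
  f_slow <- vapply(1:6, function(s) first_rip_force(10, 500 + s), numeric(1))
  f_fast <- vapply(1:6, function(s) first_rip_force(80, 600 + s), numeric(1))
  expect_gt(mean(f_fast, na.rm = TRUE), mean(f_slow, na.rm = TRUE))
})

test_that("bead-noise generator is deterministic with the exact OU spectrum", {
  a <- simulate_bead_noise(0.25, 1e-4, 5000, 5, seed = 1)
  b <- simulate_bead_noise(0.25, 1e-4, 5000, 5, seed = 1)
  expect_identical(a$position_nm, b$position_nm)
  expect_equal(stats::var(a$position_nm), kbt() / 0.25, tolerance = 0.05)
  # lag-1 autocorrelation matches exp(-theta dt)
  rho_hat <- stats::cor(a$position_nm[-1], a$position_nm[-nrow(a)])
  expect_equal(rho_hat, exp(-0.25 / 1e-4 / 5000), tolerance = 0.02)
})

test_that("benchmark suite writes scenarios with faithful ground truth", {
  dir <- withr::local_tempdir()
  params <- template_complex_params()
  rows <- params[params$mutation %in% c("WT", "L247A/T248G"), ]
  expect_warning(
    manifest <- generate_benchmark_suite(rows, dir, seed = 5,
                                         forces_pN = 5.1, duration_s = 2),
    "skipping"
  )
  wt <- manifest$scenarios$WT
  expect_equal(wt$unfolding_energy_kbt, 5.2)
  expect_equal(wt$unfolding_rate0_per_s, 0.7)
  expect_equal(wt$folding_rate0_per_s, 0.7 * exp(5.2), tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, wt$files[1])))
  # reproducibility: the manifest is byte-identical for the same seed
  dir2 <- withr::local_tempdir()
  suppressWarnings(generate_benchmark_suite(rows, dir2, seed = 5,
                                            forces_pN = 5.1, duration_s = 2))
  expect_identical(
    readLines(file.path(dir, "manifest.json")),
    readLines(file.path(dir2, "manifest.json"))
  )
  # empty table gives an empty manifest
  empty <- generate_benchmark_suite(params[0, ], withr::local_tempdir(),
                                    seed = 5)
  expect_length(empty$scenarios, 0L)
})
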