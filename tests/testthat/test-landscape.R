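scen <- wt_scenario()
sts <- function() list(f = scen$state_folded, u = scen$state_unfolded)
D8 <- separation_for_mean_force(scen, seq(4.0, 6.5, length.out = 8))
mech8 <- mechanical_energy_difference(
  scen$state_folded, scen$state_unfolded, scen$traps, scen$handle, D8
)

# binomially sampled occupancies at a given generating unfolding energy
sample_occupancies <- function(dv, n_dwells = 200, seed = 1) {
  p <- stats::plogis(mech8 - dv)
  withr::with_seed(seed, obs <- stats::rbinom(length(p), n_dwells, p) / n_dwells)
  tibble::tibble(
    trap_separation_nm = D8,
    occupancy_unfolded = obs,
    n_dwells = n_dwells
  )
}

test_that("Boltzmann fit recovers the generating unfolding energy", {
  st <- sample_occupancies(5.2, n_dwells = 400, seed = 2)
  bf <- boltzmann_fit(st, scen$state_folded, scen$state_unfolded,
                      scen$traps, scen$handle)
  expect_equal(bf$unfolding_energy_kbt, 5.2, tolerance = 0.3 / 5.2)
  # noiseless occupancies are recovered to numerical precision
  exact <- tibble::tibble(
    trap_separation_nm = D8,
    occupancy_unfolded = stats::plogis(mech8 - 5.2),
    n_dwells = 100
  )
  bf0 <- boltzmann_fit(exact, scen$state_folded, scen$state_unfolded,
                       scen$traps, scen$handle)
  expect_equal(bf0$unfolding_energy_kbt, 5.2, tolerance = 1e-5)
  # quadrupling the observations halves the standard error
  bf4 <- boltzmann_fit(
    dplyr::mutate(exact, n_dwells = 400),
    scen$state_folded, scen$state_unfolded, scen$traps, scen$handle
  )
  expect_equal(bf4$se_kbt / bf0$se_kbt, 0.5, tolerance = 1e-6)
})

test_that("saturated occupancy scans are rejected as unidentifiable", {
  st <- tibble::tibble(
    trap_separation_nm = D8,
    occupancy_unfolded = rep(0.999, 8),
    n_dwells = 100
  )
  expect_error(
    boltzmann_fit(st, scen$state_folded, scen$state_unfolded,
                  scen$traps, scen$handle),
    "identifiable"
  )
})

test_that("fitted energy increases monotonically with the generating energy", {
  ladder <- c(1.5, 2.8, 4.1, 5.4, 6.7)
  fits <- vapply(ladder, function(dv) {
    exact <- tibble::tibble(
      trap_separation_nm = D8,
      occupancy_unfolded = stats::plogis(mech8 - dv),
      n_dwells = 100
    )
    boltzmann_fit(exact, scen$state_folded, scen$state_unfolded,
                  scen$traps, scen$handle)$unfolding_energy_kbt
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
  expect_equal(fits, ladder, tolerance = 1e-4)
})

test_that("Boltzmann fit is unbiased with honest confidence intervals", {
  dvs <- seq(1.5, 6.7, length.out = 20)
  err <- numeric(20)
  covered <- logical(20)
  for (i in seq_along(dvs)) {
    st <- sample_occupancies(dvs[i], n_dwells = 150, seed = 100 + i)
    bf <- boltzmann_fit(st, scen$state_folded, scen$state_unfolded,
                        scen$traps, scen$handle)
    err[i] <- bf$unfolding_energy_kbt - dvs[i]
    covered[i] <- abs(err[i]) < 1.96 * bf$se_kbt
  }
  expect_lt(abs(mean(err)), 0.3)
  expect_gte(mean(covered), 0.9)
})

test_that("Kramers fit recovers zero-force rates and closes thermodynamically", {
  # noiseless force-dependent rates straight from the generator model
  r <- scenario_rates(scen, D8)
  st <- tibble::tibble(
    trap_separation_nm = D8,
    folding_rate_per_s = r$folding_rate_per_s,
    unfolding_rate_per_s = r$unfolding_rate_per_s,
    force_mean_pN = (r$force_folded_pN + r$force_unfolded_pN) / 2
  )
  kf <- kramers_fit(st, scen$state_folded, scen$state_unfolded,
                    scen$traps, scen$handle)
  expect_equal(kf$folding_rate_per_s, scen$folding_rate0_per_s,
               tolerance = 0.01)
  expect_equal(kf$unfolding_rate_per_s, scen$unfolding_rate0_per_s,
               tolerance = 0.01)
  expect_equal(kf$barrier_position, scen$barrier_position, tolerance = 0.05)
  # thermodynamic closure: ln(k_f0/k_u0) equals the unfolding energy
  expect_lt(
    abs(kf$unfolding_energy_kinetic_kbt - scen$unfolding_energy_kbt),
    0.5
  )
  # noisy rates: multiplicative lognormal noise, recovery within 30 %
  withr::with_seed(31, {
    noisy <- dplyr::mutate(st,
      folding_rate_per_s = folding_rate_per_s * exp(rnorm(8, 0, 0.1)),
      unfolding_rate_per_s = unfolding_rate_per_s * exp(rnorm(8, 0, 0.1))
    )
  })
  kfn <- kramers_fit(noisy, scen$state_folded, scen$state_unfolded,
                     scen$traps, scen$handle)
  expect_equal(kfn$folding_rate_per_s, scen$folding_rate0_per_s,
               tolerance = 0.3)
  expect_equal(kfn$unfolding_rate_per_s, scen$unfolding_rate0_per_s,
               tolerance = 0.3)
})

test_that("lifetime, work and unit conversions are consistent", {
  expect_equal(lifetime(0.7), 1.4, tolerance = 0.03)
  expect_identical(lifetime(1), 1)
  expect_equal(lifetime(0.2), 5, tolerance = 1e-12)
  w <- unfolding_work(5.1, 5.42)
  expect_equal(w, 5.1 * 5.42 / kbt(), tolerance = 1e-12)
  expect_equal(w, 6.7, tolerance = 0.01)
  expect_identical(unfolding_work(5.1, 0), 0)
  expect_equal(kbt_to_kcal(5.2), 5.2 * 0.593, tolerance = 1e-12)
  expect_equal(kbt_to_kcal(5.2), 3.1, tolerance = 0.01)
})

test_that("molecule aggregation gives unweighted means with SEMs", {
  tbl <- tibble::tibble(unfolding_energy_kbt = c(5.0, 5.2, 5.4))
  agg <- aggregate_molecules(tbl)
  expect_equal(agg$mean, 5.2, tolerance = 1e-12)
  expect_equal(agg$sem, 0.11547, tolerance = 1e-4)
  expect_identical(agg$n_molecules, 3L)
  # order invariance
  agg2 <- aggregate_molecules(tbl[c(3, 1, 2), ])
  expect_equal(agg, agg2)
  # single molecule: value kept, SEM absent
  one <- aggregate_molecules(tbl[1, ])
  expect_equal(one$mean, 5.0)
  expect_true(is.na(one$sem))
  expect_error(aggregate_molecules(tbl[0, ]), "empty")
})
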