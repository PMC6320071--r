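test_that("Marko-Siggia force matches direct evaluation and scaling laws", {
  seg <- wlc_segment(0.6, 20)
  expect_identical(wlc_force(seg, 0), 0)
  # direct evaluation at half extension: (kBT/P) (1/(4*0.25) + 0.5 - 0.25)
  expect_equal(wlc_force(seg, 10), kbt() / 0.6 * 1.25, tolerance = 1e-12)
  expect_equal(wlc_force(seg, 10), 8.5715, tolerance = 1e-4)
  # force scales as 1/P at fixed relative extension
  dna <- wlc_segment(40, 100)
  expect_equal(
    wlc_force(dna, 50) / wlc_force(seg, 10),
    0.6 / 40,
    tolerance = 1e-12
  )
  expect_error(wlc_force(seg, 20), "contour")
  expect_error(wlc_force(seg, -1), "contour")
})

test_that("force is strictly monotone in extension over the full domain", {
  for (par in list(c(0.6, 20), c(40, 768), c(1.2, 5))) {
    seg <- wlc_segment(par[1], par[2])
    x <- seq(0, par[2] * 0.999, length.out = 1000)
    expect_true(all(diff(wlc_force(seg, x)) > 0))
  }
})

test_that("extension inverts force to high accuracy", {
  seg <- wlc_segment(0.6, 20)
  expect_identical(wlc_extension(seg, 0), 0)
  expect_equal(wlc_extension(seg, 8.5715), 10, tolerance = 1e-4)
  # round trip over random segments and extensions
  withr::with_seed(11, {
    for (i in 1:100) {
      P <- runif(1, 0.3, 50)
      L <- runif(1, 5, 1000)
      x <- runif(1, 0, 0.98) * L
      s <- wlc_segment(P, L)
      expect_equal(wlc_extension(s, wlc_force(s, x)), x,
                   tolerance = 1e-6)
    }
  })
  # agreement with an independent bisection inverse
  f_dim <- 5.1 * 0.6 / kbt()
  expect_equal(wlc_relative_extension(5.1, 0.6), wlc_z_bisect(f_dim),
               tolerance = 1e-9)
  expect_error(wlc_extension(seg, -2), "non-negative")
})

test_that("entropic energy is the exact antiderivative of the force", {
  seg <- wlc_segment(0.6, 10)
  expect_identical(wlc_entropic_energy(seg, 0), 0)
  # closed-form value at half extension
  expect_equal(
    wlc_entropic_energy(seg, 5),
    kbt() * 10 / (4 * 0.6 * 0.5) * (3 * 0.25 - 2 * 0.125),
    tolerance = 1e-12
  )
  # quadrature of the force reproduces the closed form to < 0.1 %
  for (z in c(0.2, 0.5, 0.8, 0.95)) {
    expect_equal(
      wlc_entropic_energy(seg, z * 10),
      wlc_energy_quadrature(0.6, 10, z * 10),
      tolerance = 1e-3
    )
  }
  # derivative of the energy is the force (fundamental theorem)
  h <- 1e-6
  for (x in c(1, 4, 7, 9)) {
    dEdx <- (wlc_entropic_energy(seg, x + h) -
             wlc_entropic_energy(seg, x - h)) / (2 * h)
    expect_equal(dEdx, wlc_force(seg, x), tolerance = 1e-6)
  }
  # unit switch
  expect_equal(
    wlc_entropic_energy(seg, 5, unit = "kBT") * kbt(),
    wlc_entropic_energy(seg, 5),
    tolerance = 1e-12
  )
})

test_that("contour length bookkeeping uses 0.365 nm per residue", {
  expect_equal(contour_from_residues(54), 19.71, tolerance = 1e-9)
  expect_equal(contour_from_residues(54), 19.7, tolerance = 1e-3)
  expect_identical(contour_from_residues(0), 0)
  expect_equal(contour_from_residues(65), 23.725, tolerance = 1e-9)
  expect_identical(residues_from_contour(19.71), 54)
  expect_equal(residues_from_contour(19.8, round_to_integer = FALSE),
               19.8 / 0.365, tolerance = 1e-12)
  expect_error(contour_from_residues(-3), "non-negative")
})

test_that("tethered-ligand effective concentration reproduces published values", {
  # 54-residue linker crosslinked conjugate
  c1 <- effective_concentration(tethered_ligand(contour_from_residues(54), 6.34))
  expect_equal(c1, 3.7e-4, tolerance = 0.02)
  # 65-residue linker variant
  c2 <- effective_concentration(tethered_ligand(contour_from_residues(65), 6.34))
  expect_equal(c2, 4.3e-4, tolerance = 0.02)
})

test_that("effective concentration behaves as a Gaussian end-to-end density", {
  L <- 19.71
  p <- 0.6
  # strictly decreasing in pocket distance, maximum at R -> 0
  R <- seq(0.5, 15, length.out = 30)
  cc <- vapply(R, function(r) {
    effective_concentration(tethered_ligand(L, r, p))
  }, numeric(1))
  expect_true(all(diff(cc) < 0))
  # R -> 0 limit equals the prefactor alone
  c0 <- effective_concentration(tethered_ligand(L, 1e-9, p))
  expect_equal(c0, (3 / (4 * pi * p * L))^1.5 * 1e24 / 6.02214076e23,
               tolerance = 1e-6)
  # brute-force 3D Gaussian integral oracle at the experimental geometry
  mc <- gaussian_chain_density_mc(L, 6.34, p)
  analytic_nm3 <- effective_concentration(tethered_ligand(L, 6.34, p)) /
    (1e24 / 6.02214076e23)
  expect_equal(analytic_nm3, mc, tolerance = 5e-3)
})
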