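test_that("rectangular spectra match the closed-form overlap integral", {
  grid <- seq(350, 450, 0.25)
  donor <- spectrum(grid, rep(1, length(grid)), kind = "emission")
  eps0 <- 1.2e4
  acceptor <- spectrum(grid, rep(eps0, length(grid)), kind = "absorbance")
  J <- overlap_integral(donor, acceptor)
  l1 <- 350e-7
  l2 <- 450e-7
  J_exact <- eps0 * (l2^5 - l1^5) / (5 * (l2 - l1))
  expect_lt(abs(J - J_exact) / J_exact, 0.001)
})

test_that("zero acceptor absorptivity and disjoint bands give J = 0", {
  grid <- seq(300, 500, 0.5)
  donor <- spectrum(grid, exp(-0.5 * ((grid - 340) / 12)^2),
                    kind = "emission")
  zero <- spectrum(grid, rep(0, length(grid)), kind = "absorbance")
  expect_equal(overlap_integral(donor, zero), 0)
  far <- spectrum(seq(600, 700, 0.5), rep(1e4, 201), kind = "absorbance")
  expect_warning(J <- overlap_integral(donor, far),
                 class = "kq_no_overlap_warning")
  expect_equal(J, 0)
})

test_that("Gaussian overlap matches a 10x-resolution quadrature", {
  sim <- simulate_fret_spectra(simulation_scenario())
  J <- overlap_integral(sim$donor, sim$acceptor)
  J_ref <- attr(sim, "truth")$J_M_cm3
  expect_lt(abs(J - J_ref) / J_ref, 0.005)
})

test_that("J is invariant under donor rescaling", {
  sim <- simulate_fret_spectra(simulation_scenario())
  scaled <- spectrum(sim$donor$wavelength_nm, sim$donor$value * 37,
                     kind = "emission")
  expect_equal(overlap_integral(scaled, sim$acceptor),
               overlap_integral(sim$donor, sim$acceptor),
               tolerance = 1e-12)
})

test_that("Forster radius follows the sixth-root arithmetic and scaling law", {
  J <- 1e-14
  R0 <- forster_radius(J, 2 / 3, 1.336, 0.118)
  # independent arithmetic oracle
  oracle <- (8.79e-25 * (2 / 3) * 1.336^-4 * 0.118 * J)^(1 / 6) * 1e7
  expect_equal(R0, oracle, tolerance = 1e-12)
  expect_equal(forster_radius(J, 2 / 3, 1.336, 2 * 0.118) / R0, 2^(1 / 6),
               tolerance = 1e-12)
  expect_equal(forster_radius(0), 0)
})

test_that("transfer efficiency is 1 - F/F0", {
  expect_equal(transfer_efficiency(1000, 1000), 0)
  expect_equal(transfer_efficiency(0, 1000), 1)
  expect_equal(transfer_efficiency(500, 1000), 0.5)
  expect_error(transfer_efficiency(1100, 1000), class = "kq_validation_error")
})

test_that("distance inverts efficiency: r = R0 at E = 0.5, monotone in E", {
  expect_equal(donor_acceptor_distance(0.5, 3)$r_nm, 3, tolerance = 1e-12)
  E <- seq(0.05, 0.95, 0.05)
  r <- vapply(E, function(e) donor_acceptor_distance(e, 3)$r_nm, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_error(donor_acceptor_distance(0, 3), class = "kq_domain_error")
  expect_error(donor_acceptor_distance(1, 3), class = "kq_domain_error")
})

test_that("forward-model pipeline recovers a chosen distance within 1%", {
  cfg <- assay_config(1e4)
  sim <- simulate_fret_spectra(simulation_scenario())
  J <- overlap_integral(sim$donor, sim$acceptor)
  R0 <- forster_radius(J, cfg$kappa_squared, cfg$refractive_index,
                       cfg$quantum_yield)
  for (r_true in c(0.5, 1, 2) * R0) {
    E_true <- R0^6 / (R0^6 + r_true^6)
    F0 <- 1000
    res <- fret_distance(sim$donor, sim$acceptor,
                         F_intensity = F0 * (1 - E_true), F0 = F0,
                         config = cfg)
    expect_lt(abs(res$r_nm - r_true) / r_true, 0.01)
    expect_equal(res$plausible_transfer, r_true < 7)
  }
})
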