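test_that("simulators are byte-deterministic under a fixed seed", {
  cfg <- fixture_config()
  sc <- simulation_scenario(noise_frac = 0.01, seed = 7)
  a <- simulate_progress_curves(sc, cfg)
  b <- simulate_progress_curves(sc, cfg)
  expect_identical(a$curves, b$curves)
  sc2 <- simulation_scenario(noise_frac = 0.01, seed = 8)
  c <- simulate_progress_curves(sc2, cfg)
  expect_false(identical(a$curves[[1]]$signal_AU, c$curves[[1]]$signal_AU))

  expect_identical(simulate_inactivation(sc), simulate_inactivation(sc))
  expect_identical(simulate_quench_titration(sc, 298),
                   simulate_quench_titration(sc, 298))
})

test_that("simulators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_inactivation(simulation_scenario(seed = 55)))
  expect_identical(.Random.seed, before)
})

test_that("every generator embeds its ground truth", {
  cfg <- fixture_config()
  sc <- simulation_scenario(mechanism = "competitive", Ki_uM = 200,
                            noise_frac = 0)
  ds <- simulate_progress_curves(sc, cfg)
  truth <- attr(ds, "truth")
  expect_equal(truth$mechanism, "competitive")
  expect_equal(truth$Ki_uM, 200)
  expect_true(is.infinite(truth$Ki_prime_uM))
  expect_equal(attr(simulate_inactivation(sc), "truth")$k_per_s,
               sc$inactivation_k_per_s)
  expect_equal(attr(simulate_fret_spectra(sc), "truth")$J_M_cm3 > 0, TRUE)
})

test_that("with S >> Km and no inhibitor the curve is near zero-order", {
  cfg <- fixture_config()
  sc <- simulation_scenario(substrate_mM_grid = 50, inhibitor_uM_grid = 0,
                            noise_frac = 0, time_s = seq(0, 120, 10))
  ds <- simulate_progress_curves(sc, cfg)
  cv <- ds$curves[[1]]
  slope_AU <- coef(lm(cv$signal_AU ~ cv$time_s))[2]
  expected <- sc$Vmax * cfg$epsilon_product * cfg$path_length_cm
  expect_lt(abs(slope_AU - expected) / expected, 0.02)
})

test_that("uninhibited initial rates trace the Michaelis-Menten hyperbola", {
  cfg <- fixture_config()
  sc <- simulation_scenario(inhibitor_uM_grid = 0, noise_frac = 0)
  rt <- rate_table(simulate_progress_curves(sc, cfg), config = cfg,
                   max_depletion_frac = 0.02)
  S <- rt$substrate_M * 1e3
  v_expected <- sc$Vmax * S / (sc$Km_mM + S)
  expect_true(all(abs(rt$v - v_expected) / v_expected < 0.01))
})

test_that("quench simulator round-trips its constants at zero noise", {
  sc <- simulation_scenario(noise_frac = 0)
  dyn <- simulate_quench_titration(sc, 298, mode = "dynamic")
  fit <- stern_volmer_fit(dyn$titration)
  expect_equal(fit$Ksv_per_M, sc$Ksv_by_T[["298"]], tolerance = 1e-9)

  sc_l <- simulation_scenario(
    Ka_by_T = c("298" = 24.86e5), n_sites = 1.10, noise_frac = 0,
    quencher_uM_grid = c(0.125, 0.25, 0.5, 1, 2.5, 5, 7.5, 10)
  )
  st <- simulate_quench_titration(sc_l, 298, mode = "static")
  dl <- double_log_fit(st$titration)
  expect_equal(dl$Ka_per_M, 24.86e5, tolerance = 1e-6)
  expect_equal(dl$n_sites, 1.10, tolerance = 1e-9)
})

test_that("combined-mode titrations across T classify as static-dynamic", {
  sc <- simulation_scenario(noise_frac = 0)
  fits <- lapply(c(298, 304, 310), function(T) {
    sim <- simulate_quench_titration(sc, T, mode = "combined")
    suppressWarnings(stern_volmer_fit(sim$titration))
  })
  expect_equal(classify_quenching(fits)$class, "static_dynamic")
})

test_that("synchronous simulator imposes the requested drift", {
  sc <- simulation_scenario(peak_shift_nm = 4, noise_frac = 0)
  out <- synchronous_shift(simulate_synchronous(sc))
  expect_equal(out$direction, "red")
  expect_equal(out$shift_nm, 4, tolerance = 0.05)

  sc_b <- simulation_scenario(peak_shift_nm = -3, noise_frac = 0)
  out_b <- synchronous_shift(simulate_synchronous(sc_b))
  expect_equal(out_b$direction, "blue")
  expect_equal(out_b$shift_nm, -3, tolerance = 0.05)
})
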