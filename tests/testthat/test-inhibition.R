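# Mechanism-typing and Ki/Ki' recovery against closed-form rate data (the
# generator here is the algebraic rate law, independent of the ODE
# simulator tested elsewhere).

test_that("competitive data give Ki with Ki' flagged infinite", {
  rates <- closed_form_rates(Ki_uM = 356.3, Ki_prime_uM = Inf,
                             I_uM = c(0, 200, 400, 800, 1600))
  fit <- fit_inhibition_model(rates)
  expect_equal(fit$mechanism, "competitive")
  expect_true(is.infinite(fit$Ki_prime_uM))
  expect_lt(abs(fit$Ki_uM - 356.3) / 356.3, 0.02)
  # brute-force cross-check: apparent Km rises linearly with [I]
  Km_app <- vapply(fit$per_level, `[[`, numeric(1), "Km_mM")
  I <- as.numeric(names(Km_app))
  expect_gt(cor(I, Km_app), 0.999)
  Vmax_lvl <- vapply(fit$per_level, `[[`, numeric(1), "Vmax")
  expect_lt(diff(range(Vmax_lvl)) / mean(Vmax_lvl), 0.01)
})

test_that("non-competitive data give nearly equal Ki and Ki'", {
  rates <- closed_form_rates(Ki_uM = 34, Ki_prime_uM = 34,
                             I_uM = c(0, 10, 25, 50))
  fit <- fit_inhibition_model(rates)
  expect_equal(fit$mechanism, "non_competitive")
  expect_lt(abs(fit$Ki_uM - fit$Ki_prime_uM) / fit$Ki_uM, 0.05)
  expect_lt(abs(fit$Ki_uM - 34) / 34, 0.02)
})

test_that("tabulated parameter sets reproduce the three reference mechanisms", {
  cfg <- fixture_config()
  cases <- list(
    list(mech = "competitive", Ki = 356.3, Kip = NA, Km = 0.30,
         kcat = 2.92, I = c(0, 200, 400, 800, 1600)),
    list(mech = "mixed", Ki = 78.3, Kip = 132.4, Km = 0.48,
         kcat = 3.89, I = c(0, 10, 25, 50, 100)),
    list(mech = "non_competitive", Ki = 34.2, Kip = 35.4, Km = 0.32,
         kcat = 3.52, I = c(0, 5, 10, 25, 50))
  )
  for (cs in cases) {
    sc <- simulation_scenario(
      mechanism = cs$mech, Km_mM = cs$Km, kcat_per_s = cs$kcat,
      Ki_uM = cs$Ki, Ki_prime_uM = if (is.na(cs$Kip)) Inf else cs$Kip,
      inhibitor_uM_grid = cs$I, noise_frac = 0
    )
    ds <- simulate_progress_curves(sc, cfg)
    fit <- fit_inhibition_model(rate_table(ds, config = cfg))
    expect_equal(fit$mechanism, cs$mech)
  }
})

test_that("mechanism classifier follows the Ki/Ki' rule table", {
  expect_equal(classify_mechanism(34.2, 35.4, 0.1), "non_competitive")
  expect_equal(classify_mechanism(78.3, 132.4, 0.1), "mixed")
  expect_equal(classify_mechanism(356.3, Inf, 0.1), "competitive")
  expect_equal(classify_mechanism(Inf, 50, 0.1), "uncompetitive")
  expect_error(classify_mechanism(Inf, Inf), class = "kq_no_inhibition_error")
  # boundary of the tolerance band
  expect_equal(classify_mechanism(100, 115, 0.15), "non_competitive")
  expect_equal(classify_mechanism(100, 116, 0.15), "mixed")
})

test_that("competitive IC50 shifts with substrate while non-competitive does not", {
  Km <- 0.5
  Vmax <- 1e-6
  Ki <- 50
  for (S in c(0.5, 2)) {
    I <- c(0, 10^seq(0.5, 3, length.out = 8))
    v_comp <- Vmax * S / (Km * (1 + I / Ki) + S)
    fit <- fit_dose_response(I * 1e-6, 100 * v_comp / v_comp[1])
    expect_lt(abs(fit$ic50_M * 1e6 - Ki * (1 + S / Km)) /
                (Ki * (1 + S / Km)), 0.03)
    v_nc <- Vmax * S / ((Km + S) * (1 + I / Ki))
    fit_nc <- fit_dose_response(I * 1e-6, 100 * v_nc / v_nc[1])
    expect_lt(abs(fit_nc$ic50_M * 1e6 - Ki) / Ki, 0.03)
  }
})

test_that("replot linearity is reported as the single-site diagnostic", {
  rates <- closed_form_rates(Ki_uM = 78.3, Ki_prime_uM = 132.4)
  fit <- fit_inhibition_model(rates)
  expect_gt(fit$replot$slope$r_squared, 0.999)
  expect_gt(fit$replot$y_intercept$r_squared, 0.999)
})
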