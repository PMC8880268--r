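test_that("Stern-Volmer fit recovers an exactly generated constant", {
  tit <- dynamic_titration(3.89e5)
  fit <- stern_volmer_fit(tit)
  expect_equal(fit$Ksv_per_M, 3.89e5, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_false(fit$intercept_flag)
})

test_that("Kq is exactly Ksv / tau0", {
  tit <- dynamic_titration(23.22e5)
  fit <- stern_volmer_fit(tit, tau0_s = 1e-8)
  expect_equal(fit$Kq_per_M_s, 23.22e13, tolerance = 1e-9)
  expect_identical(fit$Kq_per_M_s, fit$Ksv_per_M / fit$tau0_s)
})

test_that("no quenching gives Ksv = 0 and F <= 0 is rejected", {
  tit <- quench_titration(c(1, 2, 3) * 1e-7, rep(1000, 3), F0 = 1000)
  expect_equal(stern_volmer_fit(tit)$Ksv_per_M, 0)
  bad <- quench_titration(c(1, 2, 3) * 1e-7, c(900, 800, 700), F0 = 1000)
  bad$F_intensity[2] <- -1
  expect_error(stern_volmer_fit(bad), class = "kq_validation_error")
})

test_that("quenching classifier covers its whole rule table", {
  mk <- function(Ksv, T, tau0 = 1e-8) {
    stern_volmer_fit(dynamic_titration(Ksv, temperature_K = T),
                     tau0_s = tau0)
  }
  # rising Ksv, Kq >> limit -> combined static-dynamic
  up_hot <- list(mk(3.89e5, 298), mk(4.22e5, 304), mk(5.30e5, 310))
  expect_equal(classify_quenching(up_hot)$class, "static_dynamic")
  # falling Ksv -> static
  down <- list(mk(23.22e5, 298), mk(21.73e5, 304), mk(18.68e5, 310))
  expect_equal(classify_quenching(down)$class, "static")
  # rising Ksv with collisional-scale Kq (tau0 = 1e-4 s -> Kq ~ 1e9)
  up_cold <- list(mk(1e5, 298, 1e-4), mk(2e5, 304, 1e-4),
                  mk(3e5, 310, 1e-4))
  expect_equal(classify_quenching(up_cold)$class, "dynamic")
  # non-monotone -> inconclusive
  zig <- list(mk(2e5, 298), mk(3e5, 304), mk(2.5e5, 310))
  out <- classify_quenching(zig)
  expect_true(out$inconclusive)
  expect_true(is.na(out$class))
})

test_that("double-log fit recovers exactly generated Ka and n", {
  tit <- static_titration(24.86e5, 1.10)
  fit <- double_log_fit(tit)
  expect_equal(fit$Ka_per_M, 24.86e5, tolerance = 1e-9)
  expect_equal(fit$n_sites, 1.10, tolerance = 1e-9)

  unit <- static_titration(1e6, 1)
  expect_equal(double_log_fit(unit)$n_sites, 1, tolerance = 1e-9)
})

test_that("noisy double-log estimates agree with a grid-search oracle", {
  # the quench fraction must dominate the 1% intensity noise at every
  # titration point, otherwise log10((F0-F)/F) blows up at low [Q]
  Ka <- 2e6
  n <- 1.05
  Q <- c(1, 2, 4, 8, 16, 32) * 1e-6
  set.seed(21)
  F0 <- 1000
  Fi <- pmin(F0 * (1 - 1e-9),
             F0 / (1 + Ka * Q^n) * (1 + rnorm(length(Q), 0, 0.01)))
  tit <- quench_titration(Q, Fi, F0 = F0)
  fit <- double_log_fit(tit)
  expect_lt(abs(fit$Ka_per_M - Ka) / Ka, 0.15)

  y <- log10((F0 - Fi) / Fi)
  grid_lka <- seq(5, 8, by = 0.002)
  grid_n <- seq(0.5, 2, by = 0.01)
  best <- Inf
  best_lka <- NA
  for (nn in grid_n) {
    pred0 <- nn * log10(Q)
    for (lka in grid_lka) {
      sse <- sum((y - lka - pred0)^2)
      if (sse < best) {
        best <- sse
        best_lka <- lka
      }
    }
  }
  # agreement limited by the oracle's grid resolution (0.002 in log10 Ka
  # jointly with 0.01 in n)
  expect_lt(abs(log10(fit$Ka_per_M) - best_lka), 0.02)
})

test_that("unquenched points are excluded with a warning", {
  Q <- c(1, 2, 4, 8, 16) * 1e-7
  F0 <- 1000
  Fi <- c(F0, F0 / (1 + 1e6 * Q[-1]))
  tit <- quench_titration(Q, Fi, F0 = F0)
  expect_warning(fit <- double_log_fit(tit),
                 class = "kq_points_excluded_warning")
  expect_equal(fit$Ka_per_M, 1e6, tolerance = 1e-6)
})

test_that("SV and double-log constants are recovered within 2% at 1% noise", {
  Ksv <- 3.89e5
  Ka <- 24.86e5
  n <- 1.10
  Q_sv <- c(0.045, 0.15, 0.25, 0.35, 0.45, 0.5, 0.6, 0.725) * 1e-6
  Q_dl <- c(0.125, 0.25, 0.5, 1, 2.5, 5, 7.5, 10) * 1e-6
  F0 <- 1000
  set.seed(99)
  est <- replicate(50, {
    F_sv <- pmin(F0 * (1 - 1e-9),
                 F0 / (1 + Ksv * Q_sv) * (1 + rnorm(length(Q_sv), 0, 0.01)))
    F_dl <- pmin(F0 * (1 - 1e-9),
                 F0 / (1 + Ka * Q_dl^n) * (1 + rnorm(length(Q_dl), 0, 0.01)))
    c(stern_volmer_fit(quench_titration(Q_sv, F_sv, F0))$Ksv_per_M,
      double_log_fit(quench_titration(Q_dl, F_dl, F0))$Ka_per_M)
  })
  expect_lt(abs(median(est[1, ]) - Ksv) / Ksv, 0.02)
  expect_lt(abs(median(est[2, ]) - Ka) / Ka, 0.02)
})

test_that("synchronous peak shifts are detected with sub-grid precision", {
  red <- lapply(seq(286, 290, length.out = 5), function(cc) {
    gaussian_spectrum(cc, 6)
  })
  out <- synchronous_shift(red)
  expect_equal(out$direction, "red")
  expect_equal(out$shift_nm, 4, tolerance = 0.01)

  blue <- lapply(seq(286, 283, length.out = 4), function(cc) {
    gaussian_spectrum(cc, 6)
  })
  out_b <- synchronous_shift(blue)
  expect_equal(out_b$direction, "blue")
  expect_equal(out_b$shift_nm, -3, tolerance = 0.01)

  same <- lapply(1:3, function(i) gaussian_spectrum(286, 6))
  out_s <- synchronous_shift(same)
  expect_equal(out_s$direction, "none")
  expect_equal(out_s$shift_nm, 0, tolerance = 1e-9)
})

test_that("flat spectra raise a no-peak error", {
  flat <- lapply(1:2, function(i) {
    spectrum(seq(260, 320, 1), rep(1, 61), kind = "synchronous",
             delta_lambda_nm = 15)
  })
  expect_error(synchronous_shift(flat), class = "kq_no_peak_error")
})
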