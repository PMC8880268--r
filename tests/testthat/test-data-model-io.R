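test_that("assay_config validates its invariants", {
  cfg <- assay_config(epsilon_product = 1e4)
  expect_equal(cfg$gas_constant_R, 8.314)
  expect_equal(cfg$tau0_s, 1e-8)
  expect_error(assay_config(-1), class = "kq_validation_error")
  expect_error(assay_config(1e4, kappa_squared = 5),
               class = "kq_validation_error")
  expect_error(assay_config(1e4, tau0_s = 0), class = "kq_validation_error")
})

test_that("absorbance_to_product is Beer-Lambert inversion", {
  cfg <- assay_config(epsilon_product = 1, path_length_cm = 1)
  expect_equal(absorbance_to_product(0, cfg), 0)
  cfg2 <- assay_config(epsilon_product = 1.82e4, path_length_cm = 0.56)
  expect_equal(absorbance_to_product(1.82e4 * 0.56 * 1e-4, cfg2), 1e-4)
  # element-wise division oracle on a random vector
  set.seed(7)
  sig <- runif(20, 0, 2)
  expected <- vapply(sig, function(s) s / (1.82e4 * 0.56), numeric(1))
  expect_equal(absorbance_to_product(sig, cfg2), expected)
})

test_that("progress curve and dataset invariants are enforced", {
  expect_error(progress_curve(c(0, 1), c(0, 1), 1e-7, 1e-3),
               class = "kq_validation_error")
  expect_error(progress_curve(c(0, 1, 1), c(0, 1, 2), 1e-7, 1e-3),
               class = "kq_validation_error")
  expect_error(progress_curve(0:2, 0:2, 1e-7, -1e-3),
               class = "kq_validation_error")
  expect_error(kinetic_dataset(list()), class = "kq_validation_error")
  cv1 <- progress_curve(0:2, 0:2, 1e-7, 1e-3, temperature_K = 298)
  cv2 <- progress_curve(0:2, 0:2, 1e-7, 1e-3, temperature_K = 310)
  expect_warning(kinetic_dataset(list(cv1, cv2)),
                 class = "kq_mixed_temperature")
})

test_that("progress CSV reader groups conditions and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    time_s = rep(c(0, 30, 60), 2),
    signal_AU = c(0, 0.1, 0.2, 0, 0.05, 0.1),
    enzyme_M = 7.5e-8,
    substrate_M = rep(c(1e-3, 2e-3), each = 3),
    inhibitor_M = 0
  )
  write.csv(df, path, row.names = FALSE)
  ds <- read_progress_csv(path)
  expect_length(ds$curves, 2)
  expect_length(ds$curves[[1]]$time_s, 3)

  out <- withr::local_tempfile(fileext = ".csv")
  write_progress_csv(ds, out)
  ds2 <- read_progress_csv(out)
  expect_equal(ds2$curves, ds$curves)
})

test_that("progress CSV reader rejects schema and invariant violations", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 0:2, signal_AU = 0:2), path,
            row.names = FALSE)
  err <- tryCatch(read_progress_csv(path), error = identity)
  expect_s3_class(err, "kq_schema_error")
  expect_match(conditionMessage(err), "enzyme_M")

  bad <- data.frame(time_s = 0:2, signal_AU = 0:2, enzyme_M = 1e-7,
                    substrate_M = -1e-3, inhibitor_M = 0)
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_progress_csv(path), class = "kq_validation_error")

  dup <- data.frame(time_s = c(0, 30, 30), signal_AU = 0:2, enzyme_M = 1e-7,
                    substrate_M = 1e-3, inhibitor_M = 0)
  write.csv(dup, path, row.names = FALSE)
  expect_error(read_progress_csv(path), class = "kq_validation_error")
})

test_that("spectrum reader sorts, rejects duplicates, round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(wavelength_nm = c(400, 300), value = c(0.5, 1)),
            path, row.names = FALSE)
  sp <- read_spectrum_csv(path)
  expect_length(sp$wavelength_nm, 2)
  expect_equal(sp$wavelength_nm, c(300, 400))
  expect_equal(sp$value, c(1, 0.5))

  write.csv(data.frame(wavelength_nm = c(300, 300), value = c(1, 2)),
            path, row.names = FALSE)
  expect_error(read_spectrum_csv(path), class = "kq_validation_error")

  sp2 <- spectrum(seq(260, 320, 5), runif(13), kind = "synchronous",
                  delta_lambda_nm = 15, label = "a")
  out <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp2, out)
  expect_equal(read_spectrum_csv(out), sp2)
})

test_that("synchronous spectra require a valid delta-lambda", {
  expect_error(spectrum(1:5, 1:5, kind = "synchronous"),
               class = "kq_validation_error")
  expect_error(spectrum(1:5, 1:5, kind = "synchronous",
                        delta_lambda_nm = 30),
               class = "kq_validation_error")
})

test_that("quench titration CSV round-trips and enforces invariants", {
  tit <- quench_titration(c(1, 2, 4) * 1e-7, c(900, 800, 700), F0 = 1000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_quench_csv(tit, path)
  expect_equal(read_quench_csv(path), tit)

  expect_error(quench_titration(c(1, 2, 4) * 1e-7, c(900, 1100, 700),
                                F0 = 1000),
               class = "kq_validation_error")
  expect_error(quench_titration(c(4, 2, 1) * 1e-7, c(900, 800, 700),
                                F0 = 1000),
               class = "kq_validation_error")
})

test_that("reports serialize losslessly through JSON", {
  rep <- kq_report(
    "kinetics",
    estimates = list(Ki_uM = 78.34567891234, mechanism = "mixed"),
    inputs = list(progress_csv = "x.csv"),
    config = assay_config(1e4), seed = 42L
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$estimates$Ki_uM, 78.34567891234)
  expect_equal(back$estimates$mechanism, "mixed")
  expect_equal(back$stage, "kinetics")
  expect_equal(back$seed, 42L)
})
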