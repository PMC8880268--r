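#' Assay configuration
#'
#' Bundles the physical constants an analysis needs: the extinction
#' coefficient used to convert absorbance into product concentration
#' (Beer-Lambert), the cuvette path length, the fluorophore excited-state
#' lifetime used to turn a Stern-Volmer constant into a bimolecular
#' quenching constant, and the Forster-transfer constants.
#'
#' Units are strict: molar, seconds and kelvin internally; kJ/mol appears
#' only in reported thermodynamic quantities.  The gas constant is fixed at
#' 8.314 J mol^-1 K^-1 and is not an argument.
#'
#' `epsilon_product` has no default on purpose: the extinction coefficient
#' of the chromogenic product (p-nitrophenol at 405 nm in this assay
#' family) depends on pH and instrument, so it must be stated explicitly.
#'
#' @param epsilon_product Molar extinction coefficient of the detected
#'   product, M^-1 cm^-1.
#' @param path_length_cm Optical path length, cm.
#' @param temperature_K Default assay temperature, K.
#' @param tau0_s Fluorophore excited-state lifetime tau0, s.  The default
#'   1e-8 s is the conventional value for intrinsic protein fluorescence
#'   and makes Kq = Ksv x 1e8.
#' @param kappa_squared FRET orientation factor kappa^2, in (0, 4].  2/3 is
#'   the isotropic-average convention.
#' @param refractive_index Medium refractive index (dimensionless).
#' @param quantum_yield Donor fluorescence quantum yield Phi.
#'
#' @return An object of class `assay_config`.
#' @export
#' @examples
#' cfg <- assay_config(epsilon_product = 1e4)
#' absorbance_to_product(0.5, cfg)
assay_config <- function(epsilon_product,
                         path_length_cm = 1,
                         temperature_K = 310,
                         tau0_s = 1e-8,
                         kappa_squared = 2 / 3,
                         refractive_index = 1.336,
                         quantum_yield = 0.118) {
  check_scalar_pos(epsilon_product, "epsilon_product")
  check_scalar_pos(path_length_cm, "path_length_cm")
  check_scalar_pos(temperature_K, "temperature_K")
  check_scalar_pos(tau0_s, "tau0_s")
  check_scalar_pos(kappa_squared, "kappa_squared")
  check_scalar_pos(refractive_index, "refractive_index")
  check_scalar_pos(quantum_yield, "quantum_yield")
  if (kappa_squared > 4) {
    abort_kq("`kappa_squared` must lie in (0, 4]", "kq_validation_error")
  }
  structure(
    list(
      epsilon_product = epsilon_product,
      path_length_cm = path_length_cm,
      temperature_K = temperature_K,
      tau0_s = tau0_s,
      gas_constant_R = .R_GAS,
      kappa_squared = kappa_squared,
      refractive_index = refractive_index,
      quantum_yield = quantum_yield
    ),
    class = "assay_config"
  )
}

#' @export
print.assay_config <- function(x, ...) {
  cat("<assay_config>\n")
  cat(sprintf("  epsilon_product:  %g M^-1 cm^-1\n", x$epsilon_product))
  cat(sprintf("  path_length_cm:   %g cm\n", x$path_length_cm))
  cat(sprintf("  temperature_K:    %g K\n", x$temperature_K))
  cat(sprintf("  tau0_s:           %g s\n", x$tau0_s))
  cat(sprintf("  kappa_squared:    %g\n", x$kappa_squared))
  cat(sprintf("  refractive_index: %g\n", x$refractive_index))
  cat(sprintf("  quantum_yield:    %g\n", x$quantum_yield))
  invisible(x)
}

#' Convert absorbance to product concentration
#'
#' Beer-Lambert inversion: concentration = A / (epsilon * l).  Vectorized
#' over `signal_AU`.
#'
#' @param signal_AU Absorbance readings, AU.
#' @param config An [assay_config()].
#' @return Product concentration(s), molar.
#' @export
absorbance_to_product <- function(signal_AU, config) {
  stopifnot(inherits(config, "assay_config"))
  signal_AU / (config$epsilon_product * config$path_length_cm)
}
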