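#' Spectral overlap integral J
#'
#' J = integral F(lambda) eps(lambda) lambda^4 d(lambda) /
#'     integral F(lambda) d(lambda),
#' with lambda in cm, so J carries units M^-1 cm^3 (eps in M^-1 cm^-1).
#' Both spectra are linearly interpolated onto the finer of the two grids
#' restricted to their intersection within the 300-500 nm analysis
#' window, and integrated by the trapezoidal rule.  The donor
#' normalization makes J invariant under uniform rescaling of the
#' emission spectrum.
#'
#' @param donor_emission Donor fluorescence emission [spectrum()]
#'   (arbitrary intensity units).
#' @param acceptor_epsilon Acceptor molar absorptivity [spectrum()],
#'   values in M^-1 cm^-1.
#' @param window_nm Analysis window, nm.
#' @return Overlap integral, M^-1 cm^3.  Disjoint spectra give 0 with a
#'   warning.
#' @export
overlap_integral <- function(donor_emission, acceptor_epsilon,
                             window_nm = c(300, 500)) {
  stopifnot(inherits(donor_emission, "kq_spectrum"),
            inherits(acceptor_epsilon, "kq_spectrum"))
  lo <- max(min(donor_emission$wavelength_nm),
            min(acceptor_epsilon$wavelength_nm), window_nm[1])
  hi <- min(max(donor_emission$wavelength_nm),
            max(acceptor_epsilon$wavelength_nm), window_nm[2])
  if (lo >= hi) {
    warn_kq("donor and acceptor spectra do not overlap in the analysis window; J = 0",
            "kq_no_overlap_warning")
    return(0)
  }
  step <- min(min(diff(donor_emission$wavelength_nm)),
              min(diff(acceptor_epsilon$wavelength_nm)))
  grid <- seq(lo, hi, by = step)
  Fd <- stats::approx(donor_emission$wavelength_nm, donor_emission$value,
                      xout = grid)$y
  eps <- stats::approx(acceptor_epsilon$wavelength_nm,
                       acceptor_epsilon$value, xout = grid)$y
  lam_cm <- grid * 1e-7
  num <- trapz(lam_cm, Fd * eps * lam_cm^4)
  den <- trapz(lam_cm, Fd)
  if (den <= 0) {
    warn_kq("donor emission integrates to zero in the window; J = 0",
            "kq_no_overlap_warning")
    return(0)
  }
  num / den
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Forster radius R0
#'
#' R0^6 (cm^6) = 8.79e-25 kappa^2 n^-4 Phi J, with J in M^-1 cm^3;
#' returned in nm.  R0 is the donor-acceptor separation at which transfer
#' efficiency is 50%.
#'
#' @param J_M_cm3 Overlap integral, M^-1 cm^3 (>= 0).
#' @param kappa_squared Orientation factor (2/3 for isotropic averaging).
#' @param refractive_index Medium refractive index.
#' @param quantum_yield Donor quantum yield Phi.
#' @return Forster radius, nm.
#' @export
forster_radius <- function(J_M_cm3, kappa_squared = 2 / 3,
                           refractive_index = 1.336,
                           quantum_yield = 0.118) {
  check_scalar_pos(kappa_squared, "kappa_squared")
  check_scalar_pos(refractive_index, "refractive_index")
  check_scalar_pos(quantum_yield, "quantum_yield")
  if (J_M_cm3 < 0) {
    abort_kq("`J_M_cm3` must be non-negative", "kq_domain_error")
  }
  if (J_M_cm3 == 0) return(0)
  R0_cm6 <- 8.79e-25 * kappa_squared * refractive_index^-4 *
    quantum_yield * J_M_cm3
  R0_cm6^(1 / 6) * 1e7
}

#' FRET transfer efficiency from quenched intensities
#'
#' E = 1 - F/F0, valid when donor and acceptor are at the reference
#' (typically 1:1) stoichiometry.
#'
#' @param F_intensity Donor fluorescence with acceptor present.
#' @param F0 Donor fluorescence without acceptor (> 0).
#' @return Transfer efficiency in \[0, 1\].
#' @export
transfer_efficiency <- function(F_intensity, F0) {
  check_scalar_pos(F0, "F0")
  if (any(F_intensity < 0) || any(F_intensity > F0 * (1 + 1e-12))) {
    abort_kq("F must lie in [0, F0]", "kq_validation_error")
  }
  1 - F_intensity / F0
}

#' Donor-acceptor distance from transfer efficiency
#'
#' r = R0 ((1 - E)/E)^(1/6).  Distances below 7 nm mark the regime where
#' non-radiative energy transfer is efficient (`plausible_transfer`).
#'
#' @param E Transfer efficiency, strictly inside (0, 1).
#' @param R0_nm Forster radius, nm (> 0).
#' @return An object of class `fret_result` with `E`, `R0_nm`, `r_nm`,
#'   `plausible_transfer`.
#' @export
donor_acceptor_distance <- function(E, R0_nm) {
  check_scalar_pos(R0_nm, "R0_nm")
  if (E <= 0 || E >= 1) {
    abort_kq("E must lie strictly inside (0, 1): E = 0 gives infinite distance, E = 1 zero distance",
             "kq_domain_error")
  }
  r <- R0_nm * ((1 - E) / E)^(1 / 6)
  structure(
    list(
      E = E, R0_nm = R0_nm, r_nm = r,
      plausible_transfer = r < 7
    ),
    class = "fret_result"
  )
}

#' Full FRET distance pipeline
#'
#' Chains [overlap_integral()], [forster_radius()],
#' [transfer_efficiency()] and [donor_acceptor_distance()].
#'
#' @inheritParams overlap_integral
#' @inheritParams transfer_efficiency
#' @param config An [assay_config()] supplying kappa^2, refractive index
#'   and quantum yield.
#' @return A `fret_result` with `J_M_cm3` added.
#' @export
fret_distance <- function(donor_emission, acceptor_epsilon, F_intensity, F0,
                          config, window_nm = c(300, 500)) {
  stopifnot(inherits(config, "assay_config"))
  J <- overlap_integral(donor_emission, acceptor_epsilon,
                        window_nm = window_nm)
  R0 <- forster_radius(J, config$kappa_squared, config$refractive_index,
                       config$quantum_yield)
  E <- transfer_efficiency(F_intensity, F0)
  out <- donor_acceptor_distance(E, R0)
  out$J_M_cm3 <- J
  out
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf(
    "<fret_result> E = %.3f, R0 = %.3f nm, r = %.3f nm (%splausible non-radiative transfer)\n",
    x$E, x$R0_nm, x$r_nm, if (x$plausible_transfer) "" else "not "
  ))
  invisible(x)
}
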