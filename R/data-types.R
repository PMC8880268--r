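#' Progress curve
#'
#' One timed assay trace (product absorbance vs time) with its full
#' condition annotation.  The raw material for every kinetic analysis.
#'
#' @param time_s Time points, s; strictly increasing, at least 3.
#' @param signal_AU Absorbance readings, AU; same length as `time_s`.
#' @param enzyme_M,substrate_M,inhibitor_M Condition concentrations, molar
#'   (non-negative; enzyme and substrate must be positive).
#' @param temperature_K Assay temperature, K.
#' @param compound_id Inhibitor identifier.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(time_s, signal_AU, enzyme_M, substrate_M,
                           inhibitor_M = 0, temperature_K = 310,
                           compound_id = "unknown") {
  if (length(time_s) != length(signal_AU)) {
    abort_kq("`time_s` and `signal_AU` must have the same length",
             "kq_validation_error")
  }
  if (length(time_s) < 3L) {
    abort_kq("a progress curve needs at least 3 points",
             "kq_validation_error")
  }
  if (any(diff(time_s) <= 0)) {
    abort_kq("`time_s` must be strictly increasing", "kq_validation_error")
  }
  for (nm in c("enzyme_M", "substrate_M", "inhibitor_M", "temperature_K")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort_kq(sprintf("`%s` must be a single non-negative number", nm),
               "kq_validation_error")
    }
  }
  structure(
    list(
      time_s = as.numeric(time_s),
      signal_AU = as.numeric(signal_AU),
      enzyme_M = enzyme_M,
      substrate_M = substrate_M,
      inhibitor_M = inhibitor_M,
      temperature_K = temperature_K,
      compound_id = as.character(compound_id)
    ),
    class = "progress_curve"
  )
}

#' Kinetic dataset
#'
#' A collection of [progress_curve()]s, typically one inhibitor titration
#' across a substrate grid.
#'
#' @param curves List of `progress_curve` objects (non-empty).
#' @param allow_mixed_temperature Permit curves at different temperatures
#'   without a warning.
#' @return An object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(curves, allow_mixed_temperature = FALSE) {
  if (length(curves) == 0L) {
    abort_kq("a kinetic dataset must contain at least one curve",
             "kq_validation_error")
  }
  if (!all(vapply(curves, inherits, logical(1), "progress_curve"))) {
    abort_kq("all elements must be progress_curve objects",
             "kq_validation_error")
  }
  temps <- vapply(curves, `[[`, numeric(1), "temperature_K")
  if (!allow_mixed_temperature && length(unique(temps)) > 1L) {
    warn_kq("curves span multiple temperatures", "kq_mixed_temperature")
  }
  structure(list(curves = curves), class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("<kinetic_dataset> %d curve(s)\n", length(x$curves)))
  for (cv in x$curves) {
    cat(sprintf(
      "  %s: %d pts, [E]=%.3g M, [S]=%.3g M, [I]=%.3g M, T=%g K\n",
      cv$compound_id, length(cv$time_s), cv$enzyme_M, cv$substrate_M,
      cv$inhibitor_M, cv$temperature_K
    ))
  }
  invisible(x)
}

#' Spectrum
#'
#' A wavelength series: fluorescence emission, molar absorptivity,
#' synchronous-scan intensity, or CD ellipticity.  The grid is sorted
#' ascending on construction; duplicate wavelengths are rejected.
#'
#' @param wavelength_nm Wavelength grid, nm.
#' @param value Intensity / epsilon (M^-1 cm^-1) / ellipticity values.
#' @param kind One of "emission", "absorbance", "synchronous", "cd".
#' @param delta_lambda_nm Offset between excitation and emission
#'   monochromators, nm; required for synchronous spectra and must be 15
#'   (tyrosine window) or 60 (tryptophan window).
#' @param label Free-text series label (e.g. titration step).
#' @return An object of class `kq_spectrum`.
#' @export
spectrum <- function(wavelength_nm, value,
                     kind = c("emission", "absorbance", "synchronous", "cd"),
                     delta_lambda_nm = NULL, label = "") {
  kind <- match.arg(kind)
  if (length(wavelength_nm) != length(value)) {
    abort_kq("`wavelength_nm` and `value` must have the same length",
             "kq_validation_error")
  }
  if (anyDuplicated(wavelength_nm)) {
    abort_kq("duplicate wavelengths in spectrum", "kq_validation_error")
  }
  o <- order(wavelength_nm)
  if (kind == "synchronous") {
    if (is.null(delta_lambda_nm) || !delta_lambda_nm %in% c(15, 60)) {
      abort_kq("synchronous spectra require delta_lambda_nm of 15 or 60",
               "kq_validation_error")
    }
  }
  structure(
    list(
      wavelength_nm = as.numeric(wavelength_nm)[o],
      value = as.numeric(value)[o],
      kind = kind,
      delta_lambda_nm = delta_lambda_nm,
      label = as.character(label)
    ),
    class = "kq_spectrum"
  )
}

#' @export
print.kq_spectrum <- function(x, ...) {
  cat(sprintf(
    "<kq_spectrum> kind=%s, %d pts, %g-%g nm%s%s\n",
    x$kind, length(x$wavelength_nm), min(x$wavelength_nm),
    max(x$wavelength_nm),
    if (!is.null(x$delta_lambda_nm)) {
      sprintf(", delta_lambda=%g nm", x$delta_lambda_nm)
    } else "",
    if (nzchar(x$label)) sprintf(", label=%s", x$label) else ""
  ))
  invisible(x)
}

#' Fluorescence quench titration
#'
#' Blank-subtracted fluorescence intensities at increasing quencher
#' concentrations, plus the unquenched intensity F0.
#'
#' @param quencher_M Quencher concentrations, molar; non-negative and
#'   strictly increasing, at least 3 points.
#' @param F_intensity Fluorescence at each quencher level (same length).
#' @param F0 Fluorescence at zero quencher (positive; each F must not
#'   exceed it).
#' @param temperature_K Temperature, K.
#' @return An object of class `quench_titration`.
#' @export
quench_titration <- function(quencher_M, F_intensity, F0,
                             temperature_K = 298) {
  if (length(quencher_M) != length(F_intensity)) {
    abort_kq("`quencher_M` and `F_intensity` must have the same length",
             "kq_validation_error")
  }
  if (length(quencher_M) < 3L) {
    abort_kq("a quench titration needs at least 3 points",
             "kq_insufficient_data_error")
  }
  if (any(quencher_M < 0) || any(diff(quencher_M) <= 0)) {
    abort_kq("`quencher_M` must be non-negative and strictly increasing",
             "kq_validation_error")
  }
  check_scalar_pos(F0, "F0")
  if (any(F_intensity > F0 * (1 + 1e-12))) {
    abort_kq("F must not exceed F0 (check blank subtraction)",
             "kq_validation_error")
  }
  check_scalar_pos(temperature_K, "temperature_K")
  structure(
    list(
      quencher_M = as.numeric(quencher_M),
      F_intensity = as.numeric(F_intensity),
      F0 = F0,
      temperature_K = temperature_K
    ),
    class = "quench_titration"
  )
}

#' @export
print.quench_titration <- function(x, ...) {
  cat(sprintf(
    "<quench_titration> %d pts, [Q] %.3g-%.3g M, F0=%g, T=%g K\n",
    length(x$quencher_M), min(x$quencher_M), max(x$quencher_M),
    x$F0, x$temperature_K
  ))
  invisible(x)
}
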