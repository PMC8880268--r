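#' Synchronous-fluorescence peak shift
#'
#' Localizes the emission peak of each synchronous spectrum in a titration
#' series (3-point parabolic interpolation around the grid maximum, so the
#' result is not limited to the wavelength grid resolution) and reports
#' the shift from the first to the last series.  A red shift (toward
#' longer wavelength) indicates increased polarity / solvent exposure of
#' the probed residues; a blue shift the opposite.  At delta-lambda 15 nm
#' the probe is the tyrosine microenvironment, at 60 nm tryptophan.
#'
#' @param spectra List of synchronous [spectrum()]s ordered by quencher
#'   concentration (>= 2, same delta-lambda).
#' @param threshold_nm Minimum |shift| to call a direction, nm.
#' @return An object of class `shift_result` with `peak_nm_by_series`,
#'   `shift_nm` (last - first), `direction` ("red", "blue", "none"),
#'   `delta_lambda_nm`.
#' @export
synchronous_shift <- function(spectra, threshold_nm = 1) {
  if (length(spectra) < 2L) {
    abort_kq("need at least 2 spectra", "kq_insufficient_data_error")
  }
  if (!all(vapply(spectra, inherits, logical(1), "kq_spectrum"))) {
    abort_kq("all elements must be spectrum objects", "kq_validation_error")
  }
  kinds <- vapply(spectra, `[[`, character(1), "kind")
  if (!all(kinds == "synchronous")) {
    abort_kq("all spectra must be of kind 'synchronous'",
             "kq_validation_error")
  }
  dls <- vapply(spectra, `[[`, numeric(1), "delta_lambda_nm")
  if (length(unique(dls)) != 1L) {
    abort_kq("spectra mix delta_lambda values", "kq_validation_error")
  }
  peaks <- vapply(spectra, function(s) {
    peak_position(s$wavelength_nm, s$value)
  }, numeric(1))
  shift <- peaks[length(peaks)] - peaks[1]
  direction <- if (shift > threshold_nm) {
    "red"
  } else if (shift < -threshold_nm) {
    "blue"
  } else {
    "none"
  }
  structure(
    list(
      peak_nm_by_series = peaks,
      shift_nm = shift,
      direction = direction,
      delta_lambda_nm = dls[1],
      threshold_nm = threshold_nm
    ),
    class = "shift_result"
  )
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "<shift_result> delta_lambda = %g nm: peak %0.2f -> %0.2f nm, shift = %+.2f nm (%s)\n",
    x$delta_lambda_nm, x$peak_nm_by_series[1],
    x$peak_nm_by_series[length(x$peak_nm_by_series)], x$shift_nm,
    x$direction
  ))
  invisible(x)
}
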