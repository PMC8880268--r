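#' Michaelis-Menten fit
#'
#' Nonlinear least squares of v = Vmax * S / (Km + S) (Levenberg-
#' Marquardt, started from the double-reciprocal line).  Substrate is in
#' mM so that Km is reported in mM, the conventional scale for this assay.
#'
#' A conditioning warning is raised when the fitted Km lands well outside
#' the tested substrate range (all S >> Km or all S << Km), where the two
#' parameters are barely identifiable.
#'
#' @param S_mM Substrate concentrations, mM (>= 4 levels recommended).
#' @param v Initial velocities, M/s.
#' @param enzyme_M Enzyme concentration, molar; enables kcat = Vmax / [E].
#' @return An object of class `mm_fit` with `Km_mM`, `Vmax`, `kcat_per_s`,
#'   `kcat_over_Km` (s^-1 mM^-1) and standard errors.
#' @export
fit_michaelis_menten <- function(S_mM, v, enzyme_M = NULL) {
  if (length(S_mM) != length(v)) {
    abort_kq("`S_mM` and `v` must have the same length",
             "kq_validation_error")
  }
  if (length(unique(S_mM)) < 4L) {
    abort_kq("need at least 4 distinct substrate levels",
             "kq_insufficient_data_error")
  }
  start <- mm_start(S_mM, v)
  df <- data.frame(S = S_mM, v = v)
  fit <- minpack.lm::nlsLM(
    v ~ Vmax * S / (Km + S), data = df,
    start = start, lower = c(Vmax = 0, Km = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- summary(fit)$coefficients
  Vmax <- co["Vmax", "Estimate"]
  Km <- co["Km", "Estimate"]
  if (Km > 3 * max(S_mM) || Km < min(S_mM) / 3) {
    warn_kq(
      "fitted Km is outside the tested substrate range; Km and Vmax are poorly identifiable",
      "kq_conditioning_warning"
    )
  }
  kcat <- if (!is.null(enzyme_M)) Vmax / enzyme_M else NA_real_
  se_kcat <- if (!is.null(enzyme_M)) co["Vmax", "Std. Error"] / enzyme_M else
    NA_real_
  structure(
    list(
      Km_mM = Km, Vmax = Vmax,
      se_Km_mM = co["Km", "Std. Error"], se_Vmax = co["Vmax", "Std. Error"],
      kcat_per_s = kcat, se_kcat_per_s = se_kcat,
      kcat_over_Km = if (is.na(kcat)) NA_real_ else kcat / Km,
      enzyme_M = enzyme_M %||% NA_real_,
      r_squared = r_squared(v, stats::fitted(fit)),
      fit = fit
    ),
    class = "mm_fit"
  )
}

# Start values from the double-reciprocal line (falls back to range-based
# guesses when some velocity is non-positive).
mm_start <- function(S_mM, v) {
  if (all(v > 0)) {
    lb <- stats::lm.fit(cbind(1, 1 / S_mM), 1 / v)$coefficients
    Vmax0 <- 1 / lb[1]
    Km0 <- lb[2] * Vmax0
    if (is.finite(Vmax0) && is.finite(Km0) && Vmax0 > 0 && Km0 > 0) {
      return(list(Vmax = unname(Vmax0), Km = unname(Km0)))
    }
  }
  list(Vmax = max(v) * 1.2, Km = stats::median(S_mM))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> Km = %.4g mM, Vmax = %.4g M/s", x$Km_mM, x$Vmax))
  if (!is.na(x$kcat_per_s)) {
    cat(sprintf(", kcat = %.4g /s, kcat/Km = %.4g /s/mM",
                x$kcat_per_s, x$kcat_over_Km))
  }
  cat(sprintf(" (R^2 = %.4f)\n", x$r_squared))
  invisible(x)
}

#' Lineweaver-Burk (double-reciprocal) line
#'
#' OLS of 1/v on 1/S.  slope = Km/Vmax, y-intercept = 1/Vmax,
#' x-intercept = -1/Km.
#'
#' @inheritParams fit_michaelis_menten
#' @return A list with `slope`, `y_intercept`, `x_intercept`,
#'   `se_slope`, `se_y_intercept`, `r_squared`.
#' @export
lineweaver_burk <- function(S_mM, v) {
  if (any(v == 0)) {
    abort_kq(
      sprintf("velocity is zero at S = %s mM: double-reciprocal transform undefined",
              paste(S_mM[v == 0], collapse = ", ")),
      "kq_division_error"
    )
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = 1 / S_mM, y = 1 / v))
  # exact data give a perfect fit; summary.lm's warning about it is noise
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co["x", "Estimate"]
  yint <- co["(Intercept)", "Estimate"]
  list(
    slope = slope, y_intercept = yint, x_intercept = -yint / slope,
    se_slope = co["x", "Std. Error"],
    se_y_intercept = co["(Intercept)", "Std. Error"],
    r_squared = suppressWarnings(summary(fit))$r.squared
  )
}

#' Catalytic efficiency
#'
#' kcat / Km, in s^-1 mM^-1.
#'
#' @param kcat_per_s Turnover number, s^-1.
#' @param Km_mM Michaelis constant, mM (> 0).
#' @return Catalytic efficiency, s^-1 mM^-1.
#' @export
catalytic_efficiency <- function(kcat_per_s, Km_mM) {
  if (any(Km_mM <= 0)) {
    abort_kq("`Km_mM` must be positive", "kq_validation_error")
  }
  kcat_per_s / Km_mM
}

#' Inhibitor potency relative to a reference
#'
#' Ratio of the reference inhibitor's Ki to the test inhibitor's Ki; the
#' reference therefore scores 1 and smaller Ki scores higher.  Returned at
#' full precision; round to one decimal for tabulation.
#'
#' @param Ki_reference_uM Reference Ki, micromolar (> 0).
#' @param Ki_uM Test-compound Ki, micromolar (> 0).
#' @return Dimensionless potency ratio.
#' @export
potency_ratio <- function(Ki_reference_uM, Ki_uM) {
  if (any(Ki_reference_uM <= 0) || any(Ki_uM <= 0)) {
    abort_kq("both Ki values must be positive", "kq_validation_error")
  }
  Ki_reference_uM / Ki_uM
}
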