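#' Stern-Volmer fit
#'
#' OLS of F0/F on \[Q\]: F0/F = 1 + Ksv \[Q\].  The intercept is fitted
#' freely by default and flagged when it deviates from 1 by more than 5%
#' (a diagnostic for deviations from simple Stern-Volmer behavior);
#' `force_intercept = TRUE` constrains it to exactly 1.  The bimolecular
#' quenching constant is Kq = Ksv / tau0 by construction.
#'
#' @param titration A [quench_titration()].
#' @param tau0_s Fluorophore excited-state lifetime, s.
#' @param force_intercept Constrain the intercept to 1.
#' @return An object of class `stern_volmer_fit` with `Ksv_per_M`,
#'   `Kq_per_M_s`, `intercept`, `intercept_flag`, `se_Ksv`, `r_squared`,
#'   `temperature_K`.
#' @export
stern_volmer_fit <- function(titration, tau0_s = 1e-8,
                             force_intercept = FALSE) {
  stopifnot(inherits(titration, "quench_titration"))
  check_scalar_pos(tau0_s, "tau0_s")
  if (any(titration$F_intensity <= 0)) {
    abort_kq("all fluorescence intensities must be positive",
             "kq_validation_error")
  }
  Q <- titration$quencher_M
  y <- titration$F0 / titration$F_intensity
  if (force_intercept) {
    fit <- stats::lm(y1 ~ Q + 0, data = data.frame(Q = Q, y1 = y - 1))
    Ksv <- unname(stats::coef(fit)["Q"])
    se <- suppressWarnings(summary(fit))$coefficients["Q", "Std. Error"]
    intercept <- 1
    fitted_y <- 1 + Ksv * Q
  } else {
    fit <- stats::lm(y ~ Q, data = data.frame(Q = Q, y = y))
    Ksv <- unname(stats::coef(fit)["Q"])
    se <- suppressWarnings(summary(fit))$coefficients["Q", "Std. Error"]
    intercept <- unname(stats::coef(fit)["(Intercept)"])
    fitted_y <- stats::fitted(fit)
  }
  intercept_flag <- abs(intercept - 1) > 0.05
  if (intercept_flag) {
    warn_kq(sprintf(
      "Stern-Volmer intercept %.3f deviates from 1 by more than 5%%",
      intercept
    ), "kq_intercept_warning")
  }
  structure(
    list(
      Ksv_per_M = Ksv,
      Kq_per_M_s = Ksv / tau0_s,
      tau0_s = tau0_s,
      intercept = intercept,
      intercept_flag = intercept_flag,
      se_Ksv = se,
      r_squared = r_squared(y, fitted_y),
      temperature_K = titration$temperature_K
    ),
    class = "stern_volmer_fit"
  )
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "<stern_volmer_fit> Ksv = %.4g /M, Kq = %.4g /M/s at %g K (R^2 = %.4f)%s\n",
    x$Ksv_per_M, x$Kq_per_M_s, x$temperature_K, x$r_squared,
    if (x$intercept_flag) sprintf(" [intercept %.3f]", x$intercept) else ""
  ))
  invisible(x)
}

#' Classify the quenching mechanism across temperatures
#'
#' Discriminates static from dynamic quenching from (a) the temperature
#' trend of Ksv and (b) the magnitude of Kq relative to the
#' diffusion-controlled collisional limit (2e10 M^-1 s^-1):
#'
#' * Ksv strictly increasing with T, Kq above the limit -> combined
#'   static-dynamic quenching;
#' * Ksv strictly increasing, Kq at or below the limit -> dynamic
#'   (collisional) quenching;
#' * Ksv strictly decreasing -> static (ground-state complex) quenching,
#'   the classical signature regardless of Kq;
#' * non-monotone Ksv(T) -> inconclusive (`NA` class).
#'
#' @param fits List of [stern_volmer_fit()]s at two or more temperatures.
#' @param diffusion_limit Maximum collisional quenching constant,
#'   M^-1 s^-1.
#' @return A list with `class` ("static", "dynamic", "static_dynamic", or
#'   `NA` when inconclusive), `inconclusive`, `Ksv_trend`, and
#'   `exceeds_diffusion_limit`.
#' @export
classify_quenching <- function(fits, diffusion_limit = 2e10) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "stern_volmer_fit")))
  temps <- vapply(fits, `[[`, numeric(1), "temperature_K")
  o <- order(temps)
  Ksv <- vapply(fits, `[[`, numeric(1), "Ksv_per_M")[o]
  Kq <- vapply(fits, `[[`, numeric(1), "Kq_per_M_s")[o]
  increasing <- all(diff(Ksv) > 0)
  decreasing <- all(diff(Ksv) < 0)
  exceeds <- all(Kq > diffusion_limit)
  if (!increasing && !decreasing) {
    return(list(class = NA_character_, inconclusive = TRUE,
                Ksv_trend = "non_monotone",
                exceeds_diffusion_limit = exceeds))
  }
  cls <- if (decreasing) {
    "static"
  } else if (exceeds) {
    "static_dynamic"
  } else {
    "dynamic"
  }
  list(class = cls, inconclusive = FALSE,
       Ksv_trend = if (increasing) "increasing" else "decreasing",
       exceeds_diffusion_limit = exceeds)
}

#' Double-logarithmic binding fit
#'
#' OLS of log10((F0 - F)/F) on log10(\[Q\]): the intercept gives the
#' binding constant Ka (M^-1) and the slope the number of binding sites n.
#' Points with F equal to F0 (no quench yet) carry no information and are
#' excluded with a warning.
#'
#' @param titration A [quench_titration()].
#' @return An object of class `binding_fit` with `Ka_per_M`, `n_sites`,
#'   `se_log10_Ka`, `se_n`, `r_squared`, `temperature_K`.
#' @export
double_log_fit <- function(titration) {
  stopifnot(inherits(titration, "quench_titration"))
  Q <- titration$quencher_M
  Fi <- titration$F_intensity
  usable <- Fi < titration$F0 & Q > 0
  if (any(!usable)) {
    warn_kq(sprintf("%d point(s) with F >= F0 or [Q] = 0 excluded",
                    sum(!usable)), "kq_points_excluded_warning")
  }
  if (sum(usable) < 3L) {
    abort_kq("fewer than 3 usable points for the double-log fit",
             "kq_insufficient_data_error")
  }
  x <- log10(Q[usable])
  y <- log10((titration$F0 - Fi[usable]) / Fi[usable])
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  co <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(
      Ka_per_M = 10^co["(Intercept)", "Estimate"],
      n_sites = co["x", "Estimate"],
      se_log10_Ka = co["(Intercept)", "Std. Error"],
      se_n = co["x", "Std. Error"],
      r_squared = suppressWarnings(summary(fit))$r.squared,
      temperature_K = titration$temperature_K
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding_fit> Ka = %.4g /M, n = %.3f at %g K (R^2 = %.4f)\n",
    x$Ka_per_M, x$n_sites, x$temperature_K, x$r_squared
  ))
  invisible(x)
}
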