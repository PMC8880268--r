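#' Four-parameter logistic dose-response fit (IC50)
#'
#' Fits activity(I) = bottom + (top - bottom) / (1 + (I / IC50)^h) with
#' the top fixed at 100% (activities are normalized to the uninhibited
#' control), the bottom bounded at >= 0, and the Hill slope free.  IC50 is
#' fitted on the log10 scale.
#'
#' If the observed activities never cross 50% inside the tested range the
#' fit proceeds but is flagged as an extrapolation.
#'
#' @param inhibitor_M Inhibitor concentrations, molar; zero entries (the
#'   control) are allowed.
#' @param activity_pct Relative activities, percent of control.
#' @param top Fixed upper asymptote, percent (default 100).
#' @return An object of class `dose_response_fit` with fields `ic50_M`,
#'   `neg_log_ic50`, `hill_slope`, `bottom_pct`, `se_ic50_M`,
#'   `extrapolated`, `r_squared`.
#' @export
fit_dose_response <- function(inhibitor_M, activity_pct, top = 100) {
  if (length(inhibitor_M) != length(activity_pct)) {
    abort_kq("`inhibitor_M` and `activity_pct` must have the same length",
             "kq_validation_error")
  }
  if (length(unique(inhibitor_M[inhibitor_M > 0])) < 4L) {
    abort_kq("need at least 4 non-zero concentration levels",
             "kq_insufficient_data_error")
  }
  extrapolated <- min(activity_pct) > 50 || max(activity_pct) < 50
  if (extrapolated) {
    warn_kq("activities never cross 50% in the tested range; IC50 is an extrapolation",
            "kq_extrapolation_warning")
  }

  # start: concentration whose activity is nearest 50%
  pos <- inhibitor_M > 0
  i50 <- inhibitor_M[pos][which.min(abs(activity_pct[pos] - 50))]
  model <- function(par) {
    par[["bottom"]] +
      (top - par[["bottom"]]) / (1 + (inhibitor_M / 10^par[["p"]])^par[["h"]])
  }
  # nls.lm rather than nlsLM: full-inhibition data drive `bottom` onto its
  # zero bound, where nlsLM's post-fit model construction fails
  fit <- minpack.lm::nls.lm(
    par = c(bottom = max(0, min(activity_pct)), p = log10(i50), h = 1),
    fn = function(par) activity_pct - model(par),
    lower = c(bottom = 0, p = -12, h = 0.05),
    upper = c(bottom = top, p = 2, h = 20),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  est <- fit$par
  # standard errors from the Gauss-Newton Hessian; a parameter pinned at
  # its bound leaves a singular block, so invert the free block only
  npar <- length(est)
  sse <- sum(fit$fvec^2)
  dfree <- max(1L, length(fit$fvec) - npar)
  cov <- tryCatch(solve(fit$hessian) * sse / dfree, error = function(e) {
    h <- fit$hessian
    free <- diag(h) > max(diag(h)) * 1e-10
    cv <- matrix(NA_real_, npar, npar)
    cv[free, free] <- solve(h[free, free, drop = FALSE]) * sse / dfree
    cv
  })
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- names(est)
  p <- est[["p"]]
  ic50 <- 10^p
  se_p <- se[["p"]]
  structure(
    list(
      ic50_M = ic50,
      neg_log_ic50 = -p,
      hill_slope = est[["h"]],
      bottom_pct = est[["bottom"]],
      se_ic50_M = log(10) * ic50 * se_p,
      extrapolated = extrapolated,
      r_squared = r_squared(activity_pct, model(fit$par)),
      fit = fit
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> IC50 = %.4g M (-log10 = %.3f), hill = %.3f, bottom = %.2f%%%s\n",
    x$ic50_M, x$neg_log_ic50, x$hill_slope, x$bottom_pct,
    if (x$extrapolated) " [extrapolated]" else ""
  ))
  invisible(x)
}
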