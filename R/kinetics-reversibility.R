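#' Reversibility test from v vs \[E\] lines
#'
#' For a reversible inhibitor, plots of initial velocity against enzyme
#' concentration at several inhibitor levels are straight lines through
#' the origin whose slope decreases as \[I\] increases; an irreversible
#' (enzyme-titrating) inhibitor instead shifts the lines to a positive
#' x-intercept.  The verdict is "reversible" iff every per-level
#' intercept's confidence interval covers zero AND slopes strictly
#' decrease with inhibitor level.
#'
#' @param data Data frame with columns `enzyme_M`, `v`, `inhibitor_M`
#'   (>= 3 enzyme levels per inhibitor level, >= 2 inhibitor levels).
#' @param conf_level Confidence level for the intercept test.
#' @return An object of class `reversibility_result` with per-level
#'   `slopes`, `intercepts`, `intercept_p`, and `verdict`.
#' @export
assess_reversibility <- function(data, conf_level = 0.95) {
  need <- c("enzyme_M", "v", "inhibitor_M")
  if (!all(need %in% names(data))) {
    abort_kq(sprintf("`data` must have columns %s",
                     paste(need, collapse = ", ")),
             "kq_schema_error")
  }
  levels_I <- sort(unique(data$inhibitor_M))
  if (length(levels_I) < 2L) {
    abort_kq("need at least 2 inhibitor levels", "kq_insufficient_design_error")
  }
  res <- lapply(levels_I, function(I) {
    d <- data[data$inhibitor_M == I, , drop = FALSE]
    if (length(unique(d$enzyme_M)) < 3L) {
      abort_kq("need at least 3 enzyme levels per inhibitor level",
               "kq_insufficient_design_error")
    }
    fit <- stats::lm(v ~ enzyme_M, data = d)
    co <- suppressWarnings(summary(fit))$coefficients
    int <- co["(Intercept)", "Estimate"]
    se <- co["(Intercept)", "Std. Error"]
    p <- co["(Intercept)", "Pr(>|t|)"]
    half <- stats::qt(1 - (1 - conf_level) / 2, fit$df.residual) * se
    # exact fits give se = 0 and an NaN p-value; an intercept at machine
    # zero still counts as passing through the origin
    covers0 <- (int - half <= 0 && int + half >= 0) ||
      abs(int) <= 1e-9 * max(abs(d$v))
    list(slope = co["enzyme_M", "Estimate"], intercept = int,
         intercept_p = p, covers0 = covers0)
  })
  slopes <- vapply(res, `[[`, numeric(1), "slope")
  intercepts <- vapply(res, `[[`, numeric(1), "intercept")
  p_values <- vapply(res, `[[`, numeric(1), "intercept_p")
  origin_ok <- all(vapply(res, `[[`, logical(1), "covers0"))
  slopes_decreasing <- all(diff(slopes) < 0)
  structure(
    list(
      inhibitor_M = levels_I,
      slopes = slopes,
      intercepts = intercepts,
      intercept_p = p_values,
      origin_ok = origin_ok,
      slopes_decreasing = slopes_decreasing,
      verdict = if (origin_ok && slopes_decreasing) "reversible" else
        "not_reversible"
    ),
    class = "reversibility_result"
  )
}

#' @export
print.reversibility_result <- function(x, ...) {
  cat(sprintf("<reversibility_result> verdict = %s\n", x$verdict))
  for (i in seq_along(x$inhibitor_M)) {
    cat(sprintf("  [I] = %.3g M: slope = %.4g, intercept = %.3g (p = %.3g)\n",
                x$inhibitor_M[i], x$slopes[i], x$intercepts[i],
                x$intercept_p[i]))
  }
  invisible(x)
}
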