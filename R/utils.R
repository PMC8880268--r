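# Internal helpers: typed conditions, seeded evaluation, small numerics.

#' @keywords internal
"_PACKAGE"

# Gas constant, J mol^-1 K^-1. Fixed, not user-settable.
.R_GAS <- 8.314

abort_kq <- function(message, class, ...) {
  stop(structure(
    class = c(class, "kq_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

warn_kq <- function(message, class) {
  warning(warningCondition(message, class = c(class, "kq_warning")))
}

check_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_kq(sprintf("`%s` must be a single finite number", name),
             "kq_validation_error")
  }
  if (strict && x <= 0) {
    abort_kq(sprintf("`%s` must be strictly positive (got %g)", name, x),
             "kq_validation_error")
  }
  invisible(x)
}

# Evaluate `code` with a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Wald-Wolfowitz runs test on the signs of `x` (normal approximation).
# Returns a two-sided p-value; perfect fits (all zero residuals) give 1.
runs_test_p <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) <= 1L) return(1)
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0L || n2 == 0L) return(0)
  runs <- 1L + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((runs - mu) / sqrt(v)))
}

# R^2 that treats a zero-variance response (perfect constant fit) as 1.
r_squared <- function(observed, fitted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(1)
  1 - sum((observed - fitted)^2) / ss_tot
}

# Peak abscissa by 3-point parabolic interpolation around the grid argmax.
peak_position <- function(x, y) {
  if (diff(range(y)) == 0) {
    abort_kq("spectrum is flat: no peak to localize", "kq_no_peak_error")
  }
  i <- which.max(y)
  n <- length(y)
  if (i == 1L || i == n) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(x[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  h <- (x[i + 1L] - x[i - 1L]) / 2
  x[i] + delta * h
}

`%||%` <- function(a, b) if (is.null(a)) b else a
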