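# Tidy-CSV readers and writers.  One reading per row is the only dialect;
# wide plate layouts must be melted before import.

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_kq(
      sprintf("file '%s' is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "kq_schema_error"
    )
  }
}

#' Read progress curves from a tidy CSV
#'
#' Expects columns `time_s`, `signal_AU`, `enzyme_M`, `substrate_M`,
#' `inhibitor_M`; optional `temperature_K` and `compound_id`.  One
#' [progress_curve()] is built per unique condition group
#' (enzyme, substrate, inhibitor, temperature, compound), rows sorted by
#' time within each group.
#'
#' @param path CSV file path.
#' @param temperature_K_default Temperature assigned when the file has no
#'   `temperature_K` column, K.
#' @return A [kinetic_dataset()].
#' @export
read_progress_csv <- function(path, temperature_K_default = 310) {
  if (!file.exists(path)) {
    abort_kq(sprintf("file '%s' does not exist", path), "kq_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(
    df, c("time_s", "signal_AU", "enzyme_M", "substrate_M", "inhibitor_M"),
    path
  )
  if (is.null(df$temperature_K)) df$temperature_K <- temperature_K_default
  if (is.null(df$compound_id)) df$compound_id <- "unknown"
  key <- interaction(df$enzyme_M, df$substrate_M, df$inhibitor_M,
                     df$temperature_K, df$compound_id, drop = TRUE)
  groups <- split(df, key)
  curves <- lapply(groups, function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    if (any(diff(g$time_s) <= 0)) {
      abort_kq("non-monotone (duplicated) time within a condition group",
               "kq_validation_error")
    }
    progress_curve(
      time_s = g$time_s, signal_AU = g$signal_AU,
      enzyme_M = g$enzyme_M[1], substrate_M = g$substrate_M[1],
      inhibitor_M = g$inhibitor_M[1], temperature_K = g$temperature_K[1],
      compound_id = g$compound_id[1]
    )
  })
  names(curves) <- NULL
  kinetic_dataset(curves, allow_mixed_temperature = TRUE)
}

#' Write a kinetic dataset to a tidy CSV
#'
#' Inverse of [read_progress_csv()]; write + read round-trips losslessly
#' (up to double-precision text formatting).
#'
#' @param dataset A [kinetic_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_progress_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  rows <- lapply(dataset$curves, function(cv) {
    data.frame(
      time_s = cv$time_s, signal_AU = cv$signal_AU,
      enzyme_M = cv$enzyme_M, substrate_M = cv$substrate_M,
      inhibitor_M = cv$inhibitor_M, temperature_K = cv$temperature_K,
      compound_id = cv$compound_id
    )
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' Expects columns `wavelength_nm`, `value`; optional constant columns
#' `kind`, `delta_lambda_nm`, `label` (explicit arguments override them).
#' Rows are sorted ascending on load; duplicate wavelengths are rejected.
#'
#' @param path CSV file path.
#' @param kind,delta_lambda_nm,label Overrides for the spectrum metadata;
#'   see [spectrum()].
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, kind = NULL, delta_lambda_nm = NULL,
                              label = NULL) {
  if (!file.exists(path)) {
    abort_kq(sprintf("file '%s' does not exist", path), "kq_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("wavelength_nm", "value"), path)
  kind <- kind %||% (if (!is.null(df$kind)) df$kind[1] else "emission")
  dl <- delta_lambda_nm %||%
    (if (!is.null(df$delta_lambda_nm) && !all(is.na(df$delta_lambda_nm))) {
      df$delta_lambda_nm[1]
    } else NULL)
  label <- label %||% (if (!is.null(df$label)) df$label[1] else "")
  spectrum(df$wavelength_nm, df$value, kind = kind,
           delta_lambda_nm = dl, label = label)
}

#' Write a spectrum to CSV
#'
#' @param spec A [spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "kq_spectrum"))
  df <- data.frame(
    wavelength_nm = spec$wavelength_nm, value = spec$value,
    kind = spec$kind,
    delta_lambda_nm = spec$delta_lambda_nm %||% NA_real_,
    label = spec$label
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a quench titration from CSV
#'
#' Expects columns `quencher_M`, `F`, and optionally `temperature_K`.
#' Rows with `quencher_M == 0` define F0 (averaged if replicated); the
#' remaining rows form the titration.
#'
#' @param path CSV file path.
#' @param temperature_K_default Temperature used when the column is
#'   absent, K.
#' @return A [quench_titration()].
#' @export
read_quench_csv <- function(path, temperature_K_default = 298) {
  if (!file.exists(path)) {
    abort_kq(sprintf("file '%s' does not exist", path), "kq_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("quencher_M", "F"), path)
  tK <- if (!is.null(df$temperature_K)) df$temperature_K[1] else
    temperature_K_default
  zero <- df$quencher_M == 0
  if (!any(zero)) {
    abort_kq("no quencher_M == 0 row from which to take F0",
             "kq_schema_error")
  }
  F0 <- mean(df$F[zero])
  ser <- df[!zero, , drop = FALSE]
  ser <- ser[order(ser$quencher_M), , drop = FALSE]
  quench_titration(ser$quencher_M, ser$F, F0 = F0, temperature_K = tK)
}

#' Write a quench titration to CSV
#'
#' @param titration A [quench_titration()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quench_csv <- function(titration, path) {
  stopifnot(inherits(titration, "quench_titration"))
  df <- data.frame(
    quencher_M = c(0, titration$quencher_M),
    F = c(titration$F0, titration$F_intensity),
    temperature_K = titration$temperature_K
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structured stage report
#'
#' A serializable record of one analysis stage: its estimates plus
#' provenance (inputs, configuration, package version, seed).  Reports
#' round-trip losslessly through JSON.
#'
#' @param stage Stage name (e.g. "kinetics").
#' @param estimates Named list of fitted quantities.
#' @param inputs Named list describing the input files / objects.
#' @param config Configuration used (an [assay_config()] or plain list).
#' @param diagnostics Named list of fit diagnostics.
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `kq_report`.
#' @export
kq_report <- function(stage, estimates, inputs = list(), config = list(),
                      diagnostics = list(), seed = NA_integer_) {
  structure(
    list(
      stage = stage,
      inputs = inputs,
      config = if (inherits(config, "assay_config")) unclass(config) else
        config,
      estimates = estimates,
      diagnostics = diagnostics,
      package_version = as.character(utils::packageVersion("kinquench")),
      seed = seed
    ),
    class = "kq_report"
  )
}

#' Write / read a report as JSON
#'
#' Full double precision is preserved so that write + read is lossless.
#'
#' @param report A [kq_report()].
#' @param path JSON file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the report.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "kq_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "kq_report")
}
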