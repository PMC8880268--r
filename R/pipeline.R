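#' Run the full characterization workflow
#'
#' Chains the analysis stages over a set of input CSVs and writes one JSON
#' report per stage plus a consolidated summary.  Any stage whose inputs
#' are absent is skipped; a stage that errors is recorded and later,
#' independent stages still run.
#'
#' Stage inputs (all optional, tidy CSVs per the package readers):
#' * `progress_csv`: progress curves across a substrate x inhibitor grid
#'   (kinetics stage: rates, mechanism, Ki/Ki', IC50 at the most common
#'   substrate level).
#' * `reversibility_csv`: columns `enzyme_M`, `v`, `inhibitor_M`.
#' * `inactivation_csv`: columns `time_s`, `activity_pct` (optionally
#'   `temperature_K`).
#' * `quench_csvs`: character vector of quench titration CSVs at two or
#'   more temperatures (quench + thermodynamics stages).
#' * `donor_csv`, `acceptor_csv`: spectra for the FRET stage; the donor
#'   quench level for E is taken from the first quench titration's first
#'   point unless `fret_F`/`fret_F0` are given.
#' * `synchronous_csvs`: ordered synchronous spectra (shift stage).
#'
#' @param inputs Named list of input paths as described above.
#' @param config An [assay_config()].
#' @param outdir Output directory for JSON reports (created if needed).
#' @param seed Integer seed recorded in report provenance.
#' @param fret_F,fret_F0 Optional donor intensities for the FRET
#'   efficiency.
#' @return A list of per-stage results (class `kq_report_bundle`),
#'   invisibly; `$summary` lists stage status.
#' @export
run_characterization <- function(inputs, config, outdir, seed = 1L,
                                 fret_F = NULL, fret_F0 = NULL) {
  stopifnot(inherits(config, "assay_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list()
  status <- list()

  run_stage <- function(name, enabled, fun) {
    if (!enabled) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[name]] <<- paste("error:", conditionMessage(res))
      bundle[[name]] <<- list(error = conditionMessage(res))
    } else {
      status[[name]] <<- "ok"
      bundle[[name]] <<- res$estimates
      rep <- kq_report(name, res$estimates,
                       inputs = res$inputs, config = config,
                       diagnostics = res$diagnostics, seed = seed)
      write_report(rep, file.path(outdir, paste0(name, ".json")))
    }
    invisible(NULL)
  }

  run_stage("kinetics", !is.null(inputs$progress_csv), function() {
    ds <- read_progress_csv(inputs$progress_csv)
    rt <- rate_table(ds, config = config)
    fit <- fit_inhibition_model(rt, enzyme_M = rt$enzyme_M[1])
    per_level <- lapply(fit$per_level, function(m) {
      list(Km_mM = m$Km_mM, Vmax = m$Vmax, kcat_per_s = m$kcat_per_s,
           kcat_over_Km = m$kcat_over_Km)
    })
    # dose-response at the most frequent substrate level
    s_tab <- table(rt$substrate_M)
    s0 <- as.numeric(names(s_tab)[which.max(s_tab)])
    sub <- rt[rt$substrate_M == s0, ]
    dr <- NULL
    if (length(unique(sub$inhibitor_M[sub$inhibitor_M > 0])) >= 4L &&
        any(sub$inhibitor_M == 0)) {
      v0 <- mean(sub$v[sub$inhibitor_M == 0])
      act <- relative_activity(sub$v, v0)
      dr <- fit_dose_response(sub$inhibitor_M, act)
    }
    list(
      estimates = list(
        mechanism = fit$mechanism, Ki_uM = fit$Ki_uM,
        Ki_prime_uM = fit$Ki_prime_uM, Km_mM = fit$Km_mM,
        Vmax = fit$Vmax, per_level = per_level,
        ic50_M = if (!is.null(dr)) dr$ic50_M else NULL,
        neg_log_ic50 = if (!is.null(dr)) dr$neg_log_ic50 else NULL
      ),
      diagnostics = list(
        replot_slope_r2 = fit$replot$slope$r_squared,
        replot_yint_r2 = fit$replot$y_intercept$r_squared
      ),
      inputs = list(progress_csv = inputs$progress_csv)
    )
  })

  run_stage("reversibility", !is.null(inputs$reversibility_csv), function() {
    df <- utils::read.csv(inputs$reversibility_csv)
    rv <- assess_reversibility(df)
    list(
      estimates = list(
        verdict = rv$verdict, slopes = rv$slopes,
        intercepts = rv$intercepts, inhibitor_M = rv$inhibitor_M
      ),
      diagnostics = list(intercept_p = rv$intercept_p),
      inputs = list(reversibility_csv = inputs$reversibility_csv)
    )
  })

  run_stage("inactivation", !is.null(inputs$inactivation_csv), function() {
    df <- utils::read.csv(inputs$inactivation_csv)
    tK <- if (!is.null(df$temperature_K)) df$temperature_K[1] else
      config$temperature_K
    fit <- fit_first_order_inactivation(df$time_s, df$activity_pct,
                                        temperature_K = tK)
    list(
      estimates = list(
        k_per_s = fit$k_per_s, plateau_frac = fit$plateau_frac,
        ddG_kJ_mol = fit$ddG_kJ_mol, monophasic = fit$monophasic,
        no_inactivation = fit$no_inactivation
      ),
      diagnostics = list(r_squared_semilog = fit$r_squared_semilog,
                         runs_p = fit$runs_p),
      inputs = list(inactivation_csv = inputs$inactivation_csv)
    )
  })

  run_stage("quench", length(inputs$quench_csvs %||% character()) > 0,
            function() {
    tits <- lapply(inputs$quench_csvs, read_quench_csv)
    sv <- lapply(tits, stern_volmer_fit, tau0_s = config$tau0_s)
    dl <- lapply(tits, double_log_fit)
    qc <- if (length(sv) >= 2L) classify_quenching(sv) else NULL
    temps <- vapply(tits, `[[`, numeric(1), "temperature_K")
    thermo <- if (length(dl) >= 3L) {
      vant_hoff(vapply(dl, `[[`, numeric(1), "Ka_per_M"), temps)
    } else NULL
    list(
      estimates = list(
        temperatures_K = temps,
        Ksv_per_M = vapply(sv, `[[`, numeric(1), "Ksv_per_M"),
        Kq_per_M_s = vapply(sv, `[[`, numeric(1), "Kq_per_M_s"),
        Ka_per_M = vapply(dl, `[[`, numeric(1), "Ka_per_M"),
        n_sites = vapply(dl, `[[`, numeric(1), "n_sites"),
        quench_class = if (!is.null(qc)) qc$class else NULL,
        dH_kJ_mol = if (!is.null(thermo)) thermo$dH_kJ_mol else NULL,
        dS_J_mol_K = if (!is.null(thermo)) thermo$dS_J_mol_K else NULL,
        dG_kJ_mol_by_T = if (!is.null(thermo)) as.list(thermo$dG_kJ_mol_by_T)
          else NULL,
        force_class = if (!is.null(thermo)) thermo$force_class else NULL
      ),
      diagnostics = list(
        sv_r2 = vapply(sv, `[[`, numeric(1), "r_squared"),
        dl_r2 = vapply(dl, `[[`, numeric(1), "r_squared")
      ),
      inputs = list(quench_csvs = inputs$quench_csvs)
    )
  })

  run_stage("fret",
            !is.null(inputs$donor_csv) && !is.null(inputs$acceptor_csv),
            function() {
    donor <- read_spectrum_csv(inputs$donor_csv, kind = "emission")
    acceptor <- read_spectrum_csv(inputs$acceptor_csv, kind = "absorbance")
    Fv <- fret_F
    F0v <- fret_F0
    if (is.null(Fv) || is.null(F0v)) {
      if (length(inputs$quench_csvs %||% character()) > 0) {
        tit <- read_quench_csv(inputs$quench_csvs[[1]])
        Fv <- tit$F_intensity[1]
        F0v <- tit$F0
      } else {
        abort_kq("FRET stage needs fret_F/fret_F0 or a quench titration",
                 "kq_validation_error")
      }
    }
    fr <- fret_distance(donor, acceptor, Fv, F0v, config)
    list(
      estimates = list(
        J_M_cm3 = fr$J_M_cm3, R0_nm = fr$R0_nm, E = fr$E, r_nm = fr$r_nm,
        plausible_transfer = fr$plausible_transfer
      ),
      diagnostics = list(),
      inputs = list(donor_csv = inputs$donor_csv,
                    acceptor_csv = inputs$acceptor_csv)
    )
  })

  run_stage("shift",
            length(inputs$synchronous_csvs %||% character()) > 1, function() {
    spectra <- lapply(inputs$synchronous_csvs, read_spectrum_csv)
    sh <- synchronous_shift(spectra)
    list(
      estimates = list(
        shift_nm = sh$shift_nm, direction = sh$direction,
        delta_lambda_nm = sh$delta_lambda_nm,
        peak_nm_by_series = sh$peak_nm_by_series
      ),
      diagnostics = list(),
      inputs = list(synchronous_csvs = inputs$synchronous_csvs)
    )
  })

  if (all(vapply(status, identical, logical(1), "skipped"))) {
    abort_kq("no stage had inputs to run", "kq_validation_error")
  }
  summary_rep <- kq_report("summary", list(stages = status),
                           inputs = inputs, config = config, seed = seed)
  write_report(summary_rep, file.path(outdir, "summary.json"))
  bundle$summary <- status
  class(bundle) <- "kq_report_bundle"
  invisible(bundle)
}

#' @export
print.kq_report_bundle <- function(x, ...) {
  cat("<kq_report_bundle>\n")
  for (nm in names(x$summary)) {
    cat(sprintf("  %-14s %s\n", nm, x$summary[[nm]]))
  }
  invisible(x)
}
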