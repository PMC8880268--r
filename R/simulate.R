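#' Simulation scenario
#'
#' Ground-truth parameter bundle for all simulators.  Defaults mirror the
#' yeast alpha-glucosidase / pNPG assay this package targets: 0.075 uM
#' enzyme, 0.25-2.5 mM substrate, inhibitor grids in the tens of
#' micromolar, Km 0.48 mM and kcat 3.89 /s for the uninhibited enzyme, a
#' mixed-type inhibitor with Ki 78.3 uM and Ki' 132.4 uM, first-order
#' inactivation at 2.78e-4 /s toward a 60% plateau, Stern-Volmer and
#' binding constants in the 1e5-1e6 M^-1 range at 298/304/310 K, an
#' emission band at 337 nm, and 1% multiplicative (plate-reader CV style)
#' noise.
#'
#' Identical scenarios produce byte-identical simulator output (seeded
#' RNG, caller's stream untouched).
#'
#' @param mechanism Inhibition mechanism to simulate.
#' @param Km_mM,kcat_per_s,enzyme_M Uninhibited enzyme parameters; Vmax is
#'   kcat * \[E\].
#' @param Ki_uM,Ki_prime_uM Inhibition constants, micromolar (the
#'   mechanism overrides the irrelevant one: competitive forces Ki' = Inf,
#'   uncompetitive Ki = Inf, non-competitive Ki' = Ki).
#' @param substrate_mM_grid,inhibitor_uM_grid,enzyme_M_grid Condition
#'   grids.
#' @param time_s Sampling times for progress curves, s.
#' @param inactivation_k_per_s,plateau_frac,inactivation_time_s
#'   Inactivation truth: rate constant, activity floor (fraction of 100%),
#'   sampling grid.
#' @param Ksv_by_T,Ka_by_T Named numeric vectors (names = temperature in
#'   K) of Stern-Volmer and binding constants, M^-1.
#' @param n_sites Binding-site number for the static quench law.
#' @param quencher_uM_grid Quencher titration grid, micromolar.
#' @param dH_kJ_mol,dS_J_mol_K Binding thermodynamics truth.
#' @param emission_peak_nm,emission_width_nm Donor emission band.
#' @param acceptor_peak_nm,acceptor_width_nm,acceptor_eps_max Acceptor
#'   absorptivity band (M^-1 cm^-1 at the peak).
#' @param sync_peak_nm,peak_shift_nm,n_titration Synchronous-scan truth:
#'   starting peak, total drift (positive = red) across the series, and
#'   series length.
#' @param noise_frac Multiplicative Gaussian noise SD as a fraction of the
#'   signal.
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(mechanism = c("mixed", "competitive",
                                              "non_competitive",
                                              "uncompetitive"),
                                Km_mM = 0.48,
                                kcat_per_s = 3.89,
                                enzyme_M = 7.5e-8,
                                Ki_uM = 78.3,
                                Ki_prime_uM = 132.4,
                                substrate_mM_grid = c(0.25, 0.5, 1, 1.5, 2, 2.5),
                                inhibitor_uM_grid = c(0, 10, 25, 50, 100),
                                enzyme_M_grid = c(0.025, 0.05, 0.075, 0.125) * 1e-6,
                                time_s = seq(0, 300, by = 15),
                                inactivation_k_per_s = 2.78e-4,
                                plateau_frac = 0.6,
                                inactivation_time_s = seq(0, 21600, by = 300),
                                Ksv_by_T = c("298" = 3.89e5, "304" = 4.22e5,
                                             "310" = 5.30e5),
                                Ka_by_T = c("298" = 2.97e5, "304" = 4.54e5,
                                            "310" = 5.48e5),
                                n_sites = 1,
                                quencher_uM_grid = c(0.045, 0.15, 0.25, 0.35,
                                                     0.45, 0.50, 0.60, 0.725),
                                dH_kJ_mol = 39.23,
                                dS_J_mol_K = 121.83,
                                emission_peak_nm = 337,
                                emission_width_nm = 25,
                                acceptor_peak_nm = 360,
                                acceptor_width_nm = 30,
                                acceptor_eps_max = 1.5e4,
                                sync_peak_nm = 286,
                                peak_shift_nm = 4,
                                n_titration = 9,
                                noise_frac = 0.01,
                                seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(length(substrate_mM_grid) > 0, length(inhibitor_uM_grid) > 0,
            length(enzyme_M_grid) > 0, noise_frac >= 0)
  # effective inhibition constants implied by the mechanism
  eff <- switch(mechanism,
    competitive = c(Ki_uM, Inf),
    uncompetitive = c(Inf, Ki_prime_uM),
    non_competitive = c(Ki_uM, Ki_uM),
    mixed = c(Ki_uM, Ki_prime_uM)
  )
  structure(
    list(
      mechanism = mechanism, Km_mM = Km_mM, kcat_per_s = kcat_per_s,
      enzyme_M = enzyme_M, Vmax = kcat_per_s * enzyme_M,
      Ki_uM = eff[1], Ki_prime_uM = eff[2],
      substrate_mM_grid = substrate_mM_grid,
      inhibitor_uM_grid = inhibitor_uM_grid,
      enzyme_M_grid = enzyme_M_grid, time_s = time_s,
      inactivation_k_per_s = inactivation_k_per_s,
      plateau_frac = plateau_frac,
      inactivation_time_s = inactivation_time_s,
      Ksv_by_T = Ksv_by_T, Ka_by_T = Ka_by_T, n_sites = n_sites,
      quencher_uM_grid = quencher_uM_grid,
      dH_kJ_mol = dH_kJ_mol, dS_J_mol_K = dS_J_mol_K,
      emission_peak_nm = emission_peak_nm,
      emission_width_nm = emission_width_nm,
      acceptor_peak_nm = acceptor_peak_nm,
      acceptor_width_nm = acceptor_width_nm,
      acceptor_eps_max = acceptor_eps_max,
      sync_peak_nm = sync_peak_nm, peak_shift_nm = peak_shift_nm,
      n_titration = n_titration,
      noise_frac = noise_frac, seed = as.integer(seed)
    ),
    class = "simulation_scenario"
  )
}

# Mixed-model rate law; Inf constants drop their term.
mixed_rate <- function(S_M, I_uM, Vmax, Km_M, Ki_uM, Kip_uM) {
  fi <- if (is.finite(Ki_uM)) 1 + I_uM / Ki_uM else 1
  fip <- if (is.finite(Kip_uM)) 1 + I_uM / Kip_uM else 1
  Vmax * S_M / (Km_M * fi + S_M * fip)
}

#' Simulate substrate-depleting progress curves
#'
#' Integrates d\[P\]/dt = Vmax (S0 - P) / (Km f_i + (S0 - P) f_i') with
#' the scenario's mechanism (adaptive LSODA stepping, relative tolerance
#' 1e-8), converts product to absorbance via Beer-Lambert, and applies
#' multiplicative Gaussian noise.  The exact generating parameters are
#' attached as `attr(, "truth")`.
#'
#' @param scenario A [simulation_scenario()].
#' @param config An [assay_config()] providing epsilon and path length.
#' @return A [kinetic_dataset()] with one curve per (substrate, inhibitor)
#'   grid point.
#' @export
simulate_progress_curves <- function(scenario, config) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            inherits(config, "assay_config"))
  sc <- scenario
  with_seed(sc$seed, {
    curves <- list()
    for (I_uM in sc$inhibitor_uM_grid) {
      for (S_mM in sc$substrate_mM_grid) {
        S0 <- S_mM * 1e-3
        sol <- deSolve::ode(
          y = c(P = 0), times = sc$time_s,
          func = function(t, y, parms) {
            S <- max(S0 - y[1], 0)
            list(mixed_rate(S, I_uM, sc$Vmax, sc$Km_mM * 1e-3,
                            sc$Ki_uM, sc$Ki_prime_uM))
          },
          parms = NULL, method = "lsoda", rtol = 1e-8, atol = 1e-12
        )
        P <- sol[, "P"]
        signal <- P * config$epsilon_product * config$path_length_cm
        if (sc$noise_frac > 0) {
          signal <- signal *
            (1 + stats::rnorm(length(signal), 0, sc$noise_frac))
        }
        curves[[length(curves) + 1L]] <- progress_curve(
          time_s = sc$time_s, signal_AU = signal,
          enzyme_M = sc$enzyme_M, substrate_M = S0,
          inhibitor_M = I_uM * 1e-6,
          temperature_K = config$temperature_K,
          compound_id = sprintf("sim_%s", sc$mechanism)
        )
      }
    }
    ds <- kinetic_dataset(curves, allow_mixed_temperature = TRUE)
    attr(ds, "truth") <- list(
      mechanism = sc$mechanism, Km_mM = sc$Km_mM, Vmax = sc$Vmax,
      kcat_per_s = sc$kcat_per_s, Ki_uM = sc$Ki_uM,
      Ki_prime_uM = sc$Ki_prime_uM, enzyme_M = sc$enzyme_M,
      noise_frac = sc$noise_frac, seed = sc$seed
    )
    ds
  })
}

#' Simulate a first-order inactivation time course
#'
#' A(t) = plateau + (100 - plateau) exp(-k t), multiplicative noise,
#' truth attached.
#'
#' @param scenario A [simulation_scenario()].
#' @return Data frame with `time_s`, `activity_pct`; `attr(, "truth")`
#'   holds the generating parameters.
#' @export
simulate_inactivation <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    t <- sc$inactivation_time_s
    plateau <- 100 * sc$plateau_frac
    A <- plateau + (100 - plateau) * exp(-sc$inactivation_k_per_s * t)
    if (sc$noise_frac > 0) {
      A <- A * (1 + stats::rnorm(length(A), 0, sc$noise_frac))
    }
    A <- pmin(A, 100)
    out <- data.frame(time_s = t, activity_pct = A)
    attr(out, "truth") <- list(
      k_per_s = sc$inactivation_k_per_s, plateau_frac = sc$plateau_frac,
      noise_frac = sc$noise_frac, seed = sc$seed
    )
    out
  })
}

#' Simulate a fluorescence quench titration
#'
#' Builds a Gaussian emission band centered on the scenario's peak and
#' scales it per titration step so that the peak intensity follows the
#' chosen quench law: `"dynamic"` F0/F = 1 + Ksv(T) \[Q\]; `"static"`
#' (F0 - F)/F = Ka(T) \[Q\]^n; `"combined"` the product of both factors.
#' The titration vector is read at the band peak; noisy intensities are
#' clipped at F0 so the titration stays valid.
#'
#' @param scenario A [simulation_scenario()].
#' @param temperature_K One of the temperatures named in the scenario's
#'   `Ksv_by_T` / `Ka_by_T`.
#' @param mode Quench law, see Details.
#' @return List with `titration` (a [quench_titration()]) and `spectra`
#'   (list of emission [spectrum()]s); `attr(, "truth")` holds the
#'   generating constants.
#' @export
simulate_quench_titration <- function(scenario, temperature_K = 298,
                                      mode = c("dynamic", "static",
                                               "combined")) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  mode <- match.arg(mode)
  sc <- scenario
  tkey <- as.character(temperature_K)
  Ksv <- if (tkey %in% names(sc$Ksv_by_T)) sc$Ksv_by_T[[tkey]] else NULL
  Ka <- if (tkey %in% names(sc$Ka_by_T)) sc$Ka_by_T[[tkey]] else NULL
  if ((mode != "static" && is.null(Ksv)) ||
      (mode != "dynamic" && is.null(Ka))) {
    abort_kq(sprintf("scenario has no constants at %s K", tkey),
             "kq_validation_error")
  }
  with_seed(sc$seed + round(temperature_K), {
    Q <- sc$quencher_uM_grid * 1e-6
    F0 <- 1000
    ratio <- switch(mode,
      dynamic = 1 + Ksv * Q,
      static = 1 + Ka * Q^sc$n_sites,
      combined = (1 + Ksv * Q) * (1 + Ka * Q^sc$n_sites)
    )
    Fi <- F0 / ratio
    if (sc$noise_frac > 0) {
      Fi <- Fi * (1 + stats::rnorm(length(Fi), 0, sc$noise_frac))
      Fi <- pmin(Fi, F0 * (1 - 1e-9))
    }
    grid <- seq(sc$emission_peak_nm - 60, sc$emission_peak_nm + 60, by = 1)
    band <- exp(-0.5 * ((grid - sc$emission_peak_nm) /
                          (sc$emission_width_nm / 2.355))^2)
    spectra <- lapply(seq_along(Q), function(i) {
      spectrum(grid, Fi[i] * band, kind = "emission",
               label = sprintf("Q=%.3g M", Q[i]))
    })
    tit <- quench_titration(Q, Fi, F0 = F0, temperature_K = temperature_K)
    out <- list(titration = tit, spectra = spectra)
    attr(out, "truth") <- list(
      mode = mode, Ksv_per_M = Ksv, Ka_per_M = Ka, n_sites = sc$n_sites,
      F0 = F0, noise_frac = sc$noise_frac, seed = sc$seed
    )
    out
  })
}

#' Simulate donor emission and acceptor absorptivity spectra
#'
#' Gaussian bands on a 0.5 nm grid over 300-500 nm with configurable
#' centers and widths; the truth slot records the overlap integral
#' evaluated on a 10x finer grid (reference quadrature).
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `donor` and `acceptor` [spectrum()]s;
#'   `attr(, "truth")$J_M_cm3` is the fine-grid overlap integral.
#' @export
simulate_fret_spectra <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  grid <- seq(300, 500, by = 0.5)
  sd_d <- sc$emission_width_nm / 2.355
  sd_a <- sc$acceptor_width_nm / 2.355
  donor_v <- exp(-0.5 * ((grid - sc$emission_peak_nm) / sd_d)^2)
  acc_v <- sc$acceptor_eps_max *
    exp(-0.5 * ((grid - sc$acceptor_peak_nm) / sd_a)^2)
  donor <- spectrum(grid, donor_v, kind = "emission", label = "donor")
  acceptor <- spectrum(grid, acc_v, kind = "absorbance", label = "acceptor")
  fine <- seq(300, 500, by = 0.05)
  lam_cm <- fine * 1e-7
  Fd <- exp(-0.5 * ((fine - sc$emission_peak_nm) / sd_d)^2)
  eps <- sc$acceptor_eps_max *
    exp(-0.5 * ((fine - sc$acceptor_peak_nm) / sd_a)^2)
  J_ref <- trapz(lam_cm, Fd * eps * lam_cm^4) / trapz(lam_cm, Fd)
  out <- list(donor = donor, acceptor = acceptor)
  attr(out, "truth") <- list(J_M_cm3 = J_ref)
  out
}

#' Simulate a synchronous-fluorescence titration series
#'
#' Gaussian peaks on 260-320 nm whose center drifts linearly across the
#' series by `peak_shift_nm` in total (positive = red shift) while the
#' amplitude decays, mimicking quenching during the titration.
#'
#' @param scenario A [simulation_scenario()].
#' @param delta_lambda_nm Synchronous offset, 15 or 60 nm.
#' @return List of synchronous [spectrum()]s; `attr(, "truth")` records
#'   the imposed shift.
#' @export
simulate_synchronous <- function(scenario, delta_lambda_nm = 15) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  with_seed(sc$seed + delta_lambda_nm, {
    grid <- seq(260, 320, by = 0.5)
    n <- sc$n_titration
    centers <- sc$sync_peak_nm +
      sc$peak_shift_nm * (seq_len(n) - 1) / (n - 1)
    spectra <- lapply(seq_len(n), function(i) {
      amp <- 1000 * (1 - 0.06 * (i - 1))
      v <- amp * exp(-0.5 * ((grid - centers[i]) / 6)^2)
      if (sc$noise_frac > 0) {
        v <- v * (1 + stats::rnorm(length(v), 0, sc$noise_frac))
      }
      spectrum(grid, v, kind = "synchronous",
               delta_lambda_nm = delta_lambda_nm,
               label = sprintf("step %d", i))
    })
    attr(spectra, "truth") <- list(
      shift_nm = sc$peak_shift_nm, start_nm = sc$sync_peak_nm,
      noise_frac = sc$noise_frac, seed = sc$seed
    )
    spectra
  })
}
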