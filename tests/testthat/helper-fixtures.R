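# Shared fixture builders.  Everything is generated in code; closed-form
# rate generators here stay independent of the package's ODE simulator so
# they can serve as oracles for it.

fixture_config <- function(epsilon = 1e4) assay_config(epsilon_product = epsilon)

# Closed-form mixed-model initial rates on a substrate x inhibitor grid.
closed_form_rates <- function(Km_mM = 0.48, Vmax = 2.9175e-7,
                              Ki_uM = 78.3, Ki_prime_uM = 132.4,
                              S_mM = c(0.25, 0.5, 1, 1.5, 2, 2.5),
                              I_uM = c(0, 10, 25, 50, 100),
                              noise_frac = 0, replicates = 1, seed = NULL) {
  grid <- expand.grid(S_mM = S_mM, I_uM = I_uM,
                      rep = seq_len(replicates))
  fi <- if (is.finite(Ki_uM)) 1 + grid$I_uM / Ki_uM else 1
  fip <- if (is.finite(Ki_prime_uM)) 1 + grid$I_uM / Ki_prime_uM else 1
  v <- Vmax * grid$S_mM / (Km_mM * fi + grid$S_mM * fip)
  if (noise_frac > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v * (1 + rnorm(length(v), 0, noise_frac))
  }
  data.frame(substrate_M = grid$S_mM * 1e-3, inhibitor_M = grid$I_uM * 1e-6,
             v = v)
}

# Gaussian emission spectrum helper.
gaussian_spectrum <- function(center, width_sd, grid = seq(260, 320, 0.5),
                              amp = 1000, kind = "synchronous",
                              delta_lambda_nm = 15, label = "") {
  spectrum(grid, amp * exp(-0.5 * ((grid - center) / width_sd)^2),
           kind = kind, delta_lambda_nm = delta_lambda_nm, label = label)
}

# Quench titration generated from the double-log law.
static_titration <- function(Ka, n, Q = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6) * 1e-6,
                             F0 = 1000, temperature_K = 298) {
  quench_titration(Q, F0 / (1 + Ka * Q^n), F0 = F0,
                   temperature_K = temperature_K)
}

# Quench titration generated from the Stern-Volmer law.
dynamic_titration <- function(Ksv, Q = c(0.045, 0.15, 0.25, 0.35, 0.45,
                                         0.5, 0.6, 0.725) * 1e-6,
                              F0 = 1000, temperature_K = 298) {
  quench_titration(Q, F0 / (1 + Ksv * Q), F0 = F0,
                   temperature_K = temperature_K)
}

ref_csv <- function(name) {
  read.csv(system.file("extdata", name, package = "kinquench"))
}
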