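#' Van 't Hoff analysis of binding constants
#'
#' OLS of ln Ka on 1/T: dH = -R * slope, dS = R * intercept, and
#' dG(T) = dH - T dS for each input temperature.  Ka is used in absolute
#' M^-1; natural logarithms are used internally (base-10 plots differ only
#' by the ln 10 factor, which cancels in dH and dS).
#'
#' Two points determine the line exactly; the fit is allowed but flagged
#' as having no residual degrees of freedom.
#'
#' @param Ka_per_M Binding constants, M^-1 (>= 2, positive).
#' @param temperature_K Matching temperatures, K (distinct).
#' @return An object of class `thermo_result` with `dH_kJ_mol`,
#'   `dS_J_mol_K`, `dG_kJ_mol_by_T` (named by temperature), `force_class`,
#'   `fit_r_squared`, `no_df`.
#' @export
vant_hoff <- function(Ka_per_M, temperature_K) {
  if (length(Ka_per_M) != length(temperature_K)) {
    abort_kq("`Ka_per_M` and `temperature_K` must have the same length",
             "kq_validation_error")
  }
  if (any(Ka_per_M <= 0)) {
    abort_kq("`Ka_per_M` must be positive", "kq_domain_error")
  }
  if (length(Ka_per_M) < 2L || anyDuplicated(temperature_K)) {
    abort_kq("need at least 2 distinct temperatures",
             "kq_insufficient_data_error")
  }
  no_df <- length(Ka_per_M) == 2L
  if (no_df) {
    warn_kq("only 2 (Ka, T) pairs: Van 't Hoff line has no residual degrees of freedom",
            "kq_no_df_warning")
  }
  fit <- stats::lm(y ~ x,
                   data = data.frame(x = 1 / temperature_K,
                                     y = log(Ka_per_M)))
  cf <- stats::coef(fit)
  dH <- -.R_GAS * unname(cf["x"]) / 1000       # kJ/mol
  dS <- .R_GAS * unname(cf["(Intercept)"])     # J/mol/K
  dG <- gibbs(dH, dS, temperature_K)
  names(dG) <- as.character(temperature_K)
  structure(
    list(
      dH_kJ_mol = dH,
      dS_J_mol_K = dS,
      dG_kJ_mol_by_T = dG,
      force_class = classify_binding_forces(dH, dS),
      fit_r_squared = if (no_df) 1 else
        suppressWarnings(summary(fit))$r.squared,
      no_df = no_df
    ),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "<thermo_result> dH = %.2f kJ/mol, dS = %.2f J/mol/K, forces = %s\n",
    x$dH_kJ_mol, x$dS_J_mol_K, x$force_class
  ))
  for (tn in names(x$dG_kJ_mol_by_T)) {
    cat(sprintf("  dG(%s K) = %.2f kJ/mol\n", tn, x$dG_kJ_mol_by_T[[tn]]))
  }
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' dG = dH - T dS / 1000, in kJ/mol (dS supplied in J/mol/K).
#'
#' @param dH_kJ_mol Enthalpy change, kJ/mol.
#' @param dS_J_mol_K Entropy change, J/mol/K.
#' @param temperature_K Temperature, K (> 0); vectorized.
#' @return Free energy change(s), kJ/mol.
#' @export
gibbs <- function(dH_kJ_mol, dS_J_mol_K, temperature_K) {
  if (any(temperature_K <= 0)) {
    abort_kq("`temperature_K` must be positive", "kq_domain_error")
  }
  dH_kJ_mol - temperature_K * dS_J_mol_K / 1000
}

#' Dominant binding force from the signs of dH and dS
#'
#' Ross-Subramanian sign rules for protein-ligand association:
#' dH > 0 and dS > 0 -> hydrophobic interactions; dH < 0 and dS < 0 ->
#' van der Waals / hydrogen bonding; dH < 0 and dS > 0 -> electrostatic.
#' The remaining quadrant (dH > 0, dS < 0) has no conventional class and
#' returns "unclassified".
#'
#' @param dH_kJ_mol Enthalpy change, kJ/mol.
#' @param dS_J_mol_K Entropy change, J/mol/K.
#' @return One of "hydrophobic", "vdW_hbond", "electrostatic",
#'   "unclassified".
#' @export
classify_binding_forces <- function(dH_kJ_mol, dS_J_mol_K) {
  if (dH_kJ_mol > 0 && dS_J_mol_K > 0) return("hydrophobic")
  if (dH_kJ_mol < 0 && dS_J_mol_K < 0) return("vdW_hbond")
  if (dH_kJ_mol < 0 && dS_J_mol_K > 0) return("electrostatic")
  "unclassified"
}
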