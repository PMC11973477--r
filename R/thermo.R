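#' Thermodynamic constants for pKa cycles
#'
#' Bundles every constant entering the proton-based thermodynamic cycle: the
#' temperature, the gas constant, the gas-phase proton entropy, the
#' 1 atm -> 1 M standard-state correction, and the aqueous proton solvation
#' free energy (Tissandier-style value, -265.9 kcal/mol). Defaults reproduce
#' the commonly used aggregate proton free energy of about -270.29 kcal/mol
#' at 298.15 K.
#'
#' @param T temperature in K.
#' @param R gas constant in kcal/(mol K). The default (1.98720e-3) makes
#'   `RT ln 10 = 1.3642` kcal/mol at 298.15 K.
#' @param S0_gas_proton standard gas-phase proton entropy, cal/(mol K).
#' @param dG_1atm_to_1M standard-state correction in kcal/mol; if `NULL`
#'   (default) it is computed as `R*T*log(24.46)` (about 1.89 at 298.15 K).
#' @param dG_solv_proton aqueous solvation free energy of the proton,
#'   kcal/mol.
#' @param hartree_to_kcal Hartree -> kcal/mol conversion used on ingest.
#'
#' @return An object of class `thermo_constants`: a list with the above
#'   fields plus the derived read-only `RT` and `RT_ln10` (kcal/mol).
#' @examples
#' tc <- thermo_constants()
#' gas_phase_proton_G(tc)       # ~ -6.286
#' standard_state_correction(tc) # ~  1.894
#' proton_free_energy(tc)       # ~ -270.29
#' @export
thermo_constants <- function(T = 298.15,
                             R = 1.98720e-3,
                             S0_gas_proton = 26.05,
                             dG_1atm_to_1M = NULL,
                             dG_solv_proton = -265.9,
                             hartree_to_kcal = 627.5095) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    pk_input_error("T must be a single positive finite number (got %s)", format(T))
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0)
    pk_input_error("R must be a single positive finite number")
  if (is.null(dG_1atm_to_1M)) dG_1atm_to_1M <- R * T * log(24.46)
  vals <- c(S0_gas_proton, dG_1atm_to_1M, dG_solv_proton, hartree_to_kcal)
  if (!all(is.finite(vals)))
    pk_input_error("all thermodynamic constants must be finite")
  out <- list(T = T, R = R,
              S0_gas_proton = S0_gas_proton,
              dG_1atm_to_1M = dG_1atm_to_1M,
              dG_solv_proton = dG_solv_proton,
              hartree_to_kcal = hartree_to_kcal,
              RT = R * T,
              RT_ln10 = R * T * log(10))
  class(out) <- "thermo_constants"
  out
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("Thermodynamic constants:\n")
  cat(sprintf("  T               = %.2f K\n", x$T))
  cat(sprintf("  R               = %.5e kcal/(mol K)   (RT ln10 = %.4f kcal/mol)\n",
              x$R, x$RT_ln10))
  cat(sprintf("  S0(g, H+)       = %.2f cal/(mol K)\n", x$S0_gas_proton))
  cat(sprintf("  dG(1atm -> 1M)  = %.3f kcal/mol\n", x$dG_1atm_to_1M))
  cat(sprintf("  dG_solv(H+)     = %.1f kcal/mol\n", x$dG_solv_proton))
  cat(sprintf("  G(H+, aq)       = %.3f kcal/mol\n", proton_free_energy(x)))
  invisible(x)
}

as_thermo_constants <- function(x) {
  if (inherits(x, "thermo_constants")) return(x)
  pk_input_error("expected a 'thermo_constants' object; see thermo_constants()")
}

#' Gas-phase proton free energy
#'
#' Standard Gibbs free energy of the gas-phase proton treated as an ideal gas
#' at 1 bar: `G0 = H0 - T*S0` with `H0 = (5/2) R T`. At the defaults this is
#' -6.286 kcal/mol.
#'
#' @param constants a [thermo_constants()] object.
#' @return kcal/mol.
#' @export
gas_phase_proton_G <- function(constants = thermo_constants()) {
  tc <- as_thermo_constants(constants)
  2.5 * tc$R * tc$T - tc$T * tc$S0_gas_proton / 1000
}

#' Standard-state correction 1 atm -> 1 mol/L
#'
#' `R*T*log(24.46)` at the default temperature, about 1.89 kcal/mol; if the
#' constants carry an explicit override it is returned as-is.
#'
#' @inheritParams gas_phase_proton_G
#' @return kcal/mol.
#' @export
standard_state_correction <- function(constants = thermo_constants()) {
  as_thermo_constants(constants)$dG_1atm_to_1M
}

#' Aqueous proton free energy
#'
#' Sum of the gas-phase proton free energy, the 1 atm -> 1 M standard-state
#' correction, and the aqueous proton solvation free energy. At the defaults
#' this is -270.29 kcal/mol, the reference used by the proton-based
#' thermodynamic cycle.
#'
#' @inheritParams gas_phase_proton_G
#' @return kcal/mol.
#' @export
proton_free_energy <- function(constants = thermo_constants()) {
  tc <- as_thermo_constants(constants)
  gas_phase_proton_G(tc) + tc$dG_1atm_to_1M + tc$dG_solv_proton
}

#' Microscopic pKa from the proton-based thermodynamic cycle
#'
#' For the deprotonation `HA^n (aq) -> H+ (aq) + A^(n-1) (aq)`,
#' `pKa = [G(A) + G(H+, aq) - G(HA)] / (RT ln 10)`. Energies are kcal/mol;
#' the result is invariant under a global energy shift and antisymmetric
#' under donor/acceptor exchange.
#'
#' @param G_donor free energy of the protonated species (kcal/mol).
#' @param G_acceptor free energy of the deprotonated species (kcal/mol).
#' @inheritParams gas_phase_proton_G
#' @return pKa in log units (vectorized over donor/acceptor).
#' @examples
#' micro_pka(0, 284.93)  # ~ 10.73
#' @export
micro_pka <- function(G_donor, G_acceptor, constants = thermo_constants()) {
  tc <- as_thermo_constants(constants)
  if (!all(is.finite(G_donor)) || !all(is.finite(G_acceptor)))
    pk_input_error("free energies must be finite")
  (G_acceptor + proton_free_energy(tc) - G_donor) / tc$RT_ln10
}

#' Microscopic pKa from the water-referenced cycle
#'
#' Uses the proton-transfer reaction
#' `HA^n (aq) + H2O (aq) -> H3O+ (aq) + A^(n-1) (aq)` instead of the bare
#' proton:
#' `pKa = [G(A) + G(H3O+) - G(HA) - G(H2O) + offset] / (RT ln 10)`.
#' The hydronium and water free energies are user-supplied (computed values
#' carried in the free-energy table under reserved ids "H3O+" and "H2O").
#' `offset` is a constant hook (kcal/mol, default 0) for e.g. a
#' water-concentration standard-state term or a constant-shift correction.
#'
#' @param G_donor,G_acceptor donor/acceptor free energies, kcal/mol.
#' @param G_water,G_hydronium water and hydronium free energies, kcal/mol.
#' @param offset additive free-energy offset, kcal/mol.
#' @inheritParams gas_phase_proton_G
#' @return pKa in log units.
#' @export
micro_pka_water_cycle <- function(G_donor, G_acceptor, G_water, G_hydronium,
                                  constants = thermo_constants(), offset = 0) {
  tc <- as_thermo_constants(constants)
  vals <- c(G_donor, G_acceptor, G_water, G_hydronium, offset)
  if (!all(is.finite(vals)))
    pk_input_error("free energies and offset must be finite")
  (G_acceptor + G_hydronium - G_donor - G_water + offset) / tc$RT_ln10
}
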