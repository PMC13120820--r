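# Physical constants (CODATA 2018 exact values)
.const <- list(
  e_C        = 1.602176634e-19,   # elementary charge [C]
  N_A        = 6.02214076e23,     # Avogadro number [1/mol]
  kcal_J     = 4184,              # thermochemical kcal [J]
  faraday_C  = 1.602176634e-19 * 6.02214076e23  # [C/mol]
)

#' Energy-per-charge unit conversion for constant-field simulations
#'
#' Computes, from physical constants, the transmembrane-field conversion
#' factor between the molecular-mechanics unit kcal mol^-1 A^-1 e^-1 and
#' mV/A: one kcal/mol per elementary charge corresponds to
#' `4184 / F` volts, where `F` is the Faraday constant.
#'
#' @return The value of 1 kcal mol^-1 e^-1 expressed in millivolts
#'   (approximately 43.4 mV).
#' @examples
#' signif(kcal_per_mol_e_mV(), 3)
#' @export
kcal_per_mol_e_mV <- function() {
  1e3 * .const$kcal_J / .const$faraday_C
}

# kB*T at 298 K in kcal/mol (R = N_A * k_B = 8.31446 J/mol/K)
.kBT_298 <- 8.31446261815324 * 298 / 4184
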