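# Single source of truth for physical constants and unit conversions.
# Internal potential unit is kcal/mol per elementary charge; user-facing
# potentials are millivolts.  Every conversion in the package routes through
# these helpers so the constants cannot drift apart between modules.

.galvanic_constants <- list(
  kB           = 1.987204e-3,   # Boltzmann constant, kcal mol^-1 K^-1
  coulomb_k    = 332.0637,      # Coulomb prefactor, kcal A mol^-1 e^-2
  eV_to_kcal   = 23.0609,       # kcal mol^-1 per e.V
  T_simulation = 310,           # K, default for dynamics
  T_reference  = 298.15         # K, default for Nernst-style conversions
)

#' Physical constants used throughout the package
#'
#' Returns the immutable table of physical constants: the Boltzmann constant
#' `kB` (kcal mol^-1 K^-1), the Coulomb prefactor `coulomb_k`
#' (kcal A mol^-1 e^-2), the conversion `eV_to_kcal` (kcal mol^-1 per e.V)
#' and the two default temperatures, `T_simulation` (310 K) and
#' `T_reference` (298.15 K) used for Nernst-style printed numbers.
#'
#' @return A named list of constants.
#' @export
#' @examples
#' phys_constants()$kB
phys_constants <- function() .galvanic_constants

#' @rdname unit_conversions
#' @export
kBT <- function(temperature = .galvanic_constants$T_simulation) {
  stopifnot(temperature > 0)
  .galvanic_constants$kB * temperature
}

#' Unit conversions between millivolts and kcal/mol per elementary charge
#'
#' `mv_to_kcal()` converts a potential in mV into the energy (kcal/mol)
#' gained by a unit charge e crossing it; `kcal_to_mv()` is the inverse.
#' `kBT()` returns the thermal energy in kcal/mol at a temperature in K.
#'
#' @param phi_mV Potential in millivolts.
#' @param energy Energy per unit charge in kcal/mol/e.
#' @param temperature Temperature in kelvin.
#' @return A numeric vector in the target unit.
#' @name unit_conversions
#' @export
#' @examples
#' mv_to_kcal(178)   # ~4.10 kcal/mol for a +1e charge
#' kcal_to_mv(1)     # ~43.36 mV
mv_to_kcal <- function(phi_mV) phi_mV / 1000 * .galvanic_constants$eV_to_kcal

#' @rdname unit_conversions
#' @export
kcal_to_mv <- function(energy) energy / .galvanic_constants$eV_to_kcal * 1000
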