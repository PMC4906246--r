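#' Physical constants used throughout the package
#'
#' All unit conversions are centralized here. Energies are in kJ/mol,
#' distances in Angstrom (trajectories) or nm (density profiles),
#' voltages in mV at the user interface and volts internally,
#' charges in elementary charge units (e).
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ/mol/K (8.3144621e-3)}
#'   \item{faraday}{Faraday constant, kJ/mol/V (96.485)}
#'   \item{e_coulomb}{elementary charge, C}
#'   \item{eps0}{vacuum permittivity, F/m}
#'   \item{temperature}{default simulation temperature, K (310)}
#' }
#' @export
vs_constants <- list(
  kB        = 8.3144621e-3,   # kJ mol^-1 K^-1
  faraday   = 96.485,         # kJ mol^-1 V^-1
  e_coulomb = 1.602176634e-19,
  eps0      = 8.8541878128e-12,
  temperature = 310
)

#' Thermal energy kT in kJ/mol
#'
#' @param temperature temperature in Kelvin (default 310 K, the membrane
#'   simulation temperature).
#' @return kT in kJ/mol. At 310 K this is 2.577 kJ/mol.
#' @export
thermal_energy <- function(temperature = vs_constants$temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  vs_constants$kB * temperature
}

#' Energy of a monovalent charge across a voltage difference
#'
#' The work done on a charge q (in e) moved across a potential
#' difference V, \eqn{W = q F V}. A monovalent ion across ~100 mV gains
#' ~10 kJ/mol, the scale argument that physiological voltages can
#' reposition the pocket sodium.
#'
#' @param vm_mV voltage difference in mV.
#' @param charge carrier charge in elementary units (default +1).
#' @return energy in kJ/mol.
#' @export
charge_voltage_energy <- function(vm_mV, charge = 1) {
  charge * vs_constants$faraday * vm_mV / 1000
}
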