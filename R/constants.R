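#' Physical constants used throughout the package
#'
#' Units are kcal/mol for energies, Angstrom for lengths, Kelvin for
#' temperatures and atmospheres for pressure.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/(mol K).}
#'   \item{coulomb}{Coulomb conversion factor, kcal Angstrom/(mol e^2).}
#'   \item{atm_A3}{Energy of 1 atm x 1 Angstrom^3, kcal/mol.}
#'   \item{kB_J}{Boltzmann constant, J/K.}
#'   \item{amu_kg}{Atomic mass unit, kg.}
#'   \item{hbar}{Reduced Planck constant, J s.}
#'   \item{euler}{Euler's number squared appears in the Schlitter bound; e itself.}
#' }
#' @export
mc_constants <- list(
  kB      = 0.0019872041,
  coulomb = 332.0636,
  atm_A3  = 1.458397e-5,
  kB_J    = 1.380649e-23,
  amu_kg  = 1.66053907e-27,
  hbar    = 1.054571817e-34,
  euler   = exp(1)
)
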