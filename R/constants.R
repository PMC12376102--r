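#' Physical constants used throughout the package
#'
#' CODATA values for the Boltzmann and Planck constants; the molar gas
#' constant is taken as 8.314 J/mol/K.  Energies are handled in kJ/mol,
#' times in ps (simulation) or s (kinetics), lengths in angstrom and
#' angles in degrees.
#'
#' @format A named list with elements `kB` (J/K), `h` (J s),
#'   `R` (J/mol/K).
#' @export
phys_constants <- list(
  kB = 1.380649e-23,
  h  = 6.62607015e-34,
  R  = 8.314
)

#' Thermal energy in kJ/mol
#'
#' @param temperature temperature in K.
#' @return kB*T expressed per mole, in kJ/mol.
#' @export
kBT_kJmol <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  phys_constants$R * temperature / 1000
}
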