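#' Boltzmann constant in kcal/mol/K
#'
#' The value used throughout the package to convert temperatures to thermal
#' energies.
#'
#' @format A length-one numeric, 0.0019872041 kcal/mol/K.
#' @export
BOLTZMANN_KCAL <- 0.0019872041

#' Thermodynamic context
#'
#' Bundles the simulation temperature with the derived thermal energy
#' \eqn{kT = k_B T}. All estimators in the package take energies in kcal/mol,
#' so at the default 300 K, \eqn{kT \approx 0.59616} kcal/mol.
#'
#' @param temperature Temperature in kelvin; must be positive. Default 300.
#' @return An object of class `thermo_context` with fields `temperature`
#'   (K) and `kT` (kcal/mol).
#' @examples
#' ctx <- thermo_context()
#' ctx$kT  # ~0.596 kcal/mol
#' @export
thermo_context <- function(temperature = 300) {
  abfe_assert(is_number(temperature) && temperature > 0,
              "temperature must be a single positive number (kelvin)",
              "abfe_domain_error")
  structure(
    list(temperature = temperature, kT = BOLTZMANN_KCAL * temperature),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %g K, kT = %.5f kcal/mol\n",
              x$temperature, x$kT))
  invisible(x)
}
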