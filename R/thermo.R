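#' Thermodynamic state
#'
#' Bundles the absolute temperature with the molar gas constant and the
#' derived thermal energy \eqn{RT}. All free energies in the package are
#' molar (kJ/mol), so \eqn{RT} is the natural energy scale: at the
#' default 320 K, \eqn{RT \approx 2.6606} kJ/mol.
#'
#' @param temperature Absolute temperature in kelvin. Default 320 K.
#' @return An object of class `thermo_state`: a list with elements
#'   `temperature` (K), `molar_gas_constant` (kJ/mol/K) and `RT`
#'   (kJ/mol).
#' @examples
#' th <- thermo_state()
#' th$RT
#' @export
thermo_state <- function(temperature = 320) {
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0) {
    abort("`temperature` must be a single positive number (kelvin).")
  }
  R <- 8.314462e-3 # kJ/mol/K
  structure(
    list(temperature = temperature, molar_gas_constant = R,
         RT = R * temperature),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %g K, RT = %.5g kJ/mol\n",
              x$temperature, x$RT))
  invisible(x)
}

as_thermo <- function(thermo) {
  if (inherits(thermo, "thermo_state")) return(thermo)
  if (is.numeric(thermo) && length(thermo) == 1) return(thermo_state(thermo))
  abort("`thermo` must be a thermo_state or a temperature in kelvin.")
}
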