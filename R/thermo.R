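#' Thermodynamic parameters
#'
#' Bundles the temperature with the Boltzmann constant and the derived inverse
#' temperature. All energies in the package are in kcal mol^-1, so
#' `k_B = 0.0019872041` kcal mol^-1 K^-1 and `kBT` is in kcal mol^-1.
#'
#' @param temperature temperature in kelvin (> 0). Default 300 K.
#' @return an object of class `thermo_params` with fields `temperature`,
#'   `k_B`, `kBT` and `beta = 1/kBT`.
#' @examples
#' th <- thermo_params(300)
#' th$beta * th$k_B * th$temperature  # == 1
#' @export
thermo_params <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("`temperature` must be a single positive number (kelvin)")
  kBT <- .kB_kcal * temperature
  structure(
    list(temperature = temperature, k_B = .kB_kcal, kBT = kBT, beta = 1 / kBT),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("thermo_params: T = %g K, kBT = %.6f kcal/mol\n", x$temperature, x$kBT))
  invisible(x)
}

as_thermo <- function(x) {
  if (inherits(x, "thermo_params")) return(x)
  stop("expected a `thermo_params` object; see thermo_params()")
}
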