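#' Medium conditions for hydrodynamic sizing
#'
#' Temperature and dynamic viscosity of the suspension medium, the two
#' physical parameters (besides the Boltzmann constant) entering the
#' Stokes-Einstein relation. The default is water at 25 degrees C.
#'
#' @param temperature Absolute temperature in kelvin. Default 298.15 K.
#' @param viscosity Dynamic viscosity in pascal-seconds. Default
#'   8.9e-4 Pa s (water at 25 degrees C).
#' @return An object of class `medium_conditions`.
#' @export
#' @examples
#' medium_conditions()
#' medium_conditions(temperature = 310, viscosity = 6.9e-4)
medium_conditions <- function(temperature = 298.15, viscosity = 8.9e-4) {
  check_scalar_positive(temperature, "temperature")
  check_scalar_positive(viscosity, "viscosity")
  structure(
    list(temperature = temperature, viscosity = viscosity),
    class = "medium_conditions"
  )
}

#' @export
print.medium_conditions <- function(x, ...) {
  cat(sprintf(
    "<medium_conditions> T = %.2f K, eta = %.3g Pa s\n",
    x$temperature, x$viscosity
  ))
  invisible(x)
}

check_medium <- function(medium) {
  if (!inherits(medium, "medium_conditions")) {
    abort("`medium` must be created with medium_conditions().")
  }
  invisible(medium)
}
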