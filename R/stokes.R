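#' Convert a diffusion coefficient to a hydrodynamic diameter
#'
#' Applies the Stokes-Einstein relation in diameter form,
#' \deqn{d = \frac{k_B T}{3 \pi \eta D},}
#' the diameter equivalent of \eqn{r = k_B T / (6 \pi \eta D)}. The diameter
#' of the equivalent sphere diffusing at rate `diffusion_coeff` is returned
#' in nanometres.
#'
#' @param diffusion_coeff Diffusion coefficient(s) in um^2/s. Must be > 0.
#' @param medium A [medium_conditions()] object.
#' @return Hydrodynamic diameter(s) in nm.
#' @seealso [diameter_to_diffusion()] for the forward relation.
#' @export
#' @examples
#' # a 100 nm sphere in water at 25 C diffuses at ~4.91 um^2/s
#' stokes_einstein_diameter(4.91)
stokes_einstein_diameter <- function(diffusion_coeff, medium = medium_conditions()) {
  check_medium(medium)
  if (length(diffusion_coeff) == 0L) {
    return(numeric(0))
  }
  if (!is.numeric(diffusion_coeff) || any(is.na(diffusion_coeff)) ||
    any(diffusion_coeff <= 0)) {
    abort("`diffusion_coeff` must be positive (um^2/s).")
  }
  # D in m^2/s, d in m, then to nm
  d_m <- .kB * medium$temperature /
    (3 * pi * medium$viscosity * diffusion_coeff * 1e-12)
  d_m * 1e9
}

#' Convert a hydrodynamic diameter to a diffusion coefficient
#'
#' Forward Stokes-Einstein relation \eqn{D = k_B T / (3 \pi \eta d)}, used by
#' the Brownian-motion simulator to turn a particle diameter into the
#' diffusion coefficient that drives its random walk.
#'
#' @param diameter Hydrodynamic diameter(s) in nm. Must be > 0.
#' @inheritParams stokes_einstein_diameter
#' @return Diffusion coefficient(s) in um^2/s.
#' @export
#' @examples
#' diameter_to_diffusion(100) # ~4.91 um^2/s in water at 25 C
diameter_to_diffusion <- function(diameter, medium = medium_conditions()) {
  check_medium(medium)
  if (length(diameter) == 0L) {
    return(numeric(0))
  }
  if (!is.numeric(diameter) || any(is.na(diameter)) || any(diameter <= 0)) {
    abort("`diameter` must be positive (nm).")
  }
  D_m2s <- .kB * medium$temperature /
    (3 * pi * medium$viscosity * diameter * 1e-9)
  D_m2s * 1e12
}
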