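#' Specify an extruded liposome population
#'
#' A liposome preparation is modelled as a mixture of lognormal size
#' components with an optional hard upper truncation representing extrusion:
#' forcing vesicles through a polycarbonate filter imposes an upper size
#' limit while letting through a broad range of smaller vesicles.
#'
#' @param median_diameter Vector of component median diameters in nm.
#' @param geometric_sd Vector of component geometric standard deviations
#'   (unitless, > 1).
#' @param weight Vector of non-negative component weights; normalised to
#'   sum to 1.
#' @param extrusion_cutoff Upper diameter truncation in nm (the filter pore
#'   size), or `NULL` for no truncation.
#' @param concentration Nominal particle concentration in particles/ml.
#' @return An object of class `population_spec`.
#' @export
#' @examples
#' # an 800-nm-extruded polydisperse preparation
#' population_spec(220, 1.5, extrusion_cutoff = 800)
population_spec <- function(median_diameter, geometric_sd, weight = NULL,
                            extrusion_cutoff = NULL, concentration = 3e8) {
  k <- length(median_diameter)
  if (k == 0L || length(geometric_sd) != k) {
    abort("`median_diameter` and `geometric_sd` must have equal positive length.")
  }
  if (any(median_diameter <= 0)) abort("median diameters must be positive.")
  if (any(geometric_sd <= 1)) abort("geometric SDs must be > 1.")
  weight <- weight %||% rep(1, k)
  if (length(weight) != k || any(weight < 0) || sum(weight) <= 0) {
    abort("`weight` must be non-negative with a positive sum.")
  }
  if (!is.null(extrusion_cutoff)) {
    check_scalar_positive(extrusion_cutoff, "extrusion_cutoff")
  }
  check_scalar_positive(concentration, "concentration")
  structure(
    list(
      median_diameter = as.numeric(median_diameter),
      geometric_sd = as.numeric(geometric_sd),
      weight = weight / sum(weight),
      extrusion_cutoff = extrusion_cutoff,
      concentration = concentration
    ),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat("<population_spec>\n")
  for (i in seq_along(x$median_diameter)) {
    cat(sprintf(
      "  component %d: median %.0f nm, gsd %.2f, weight %.2f\n",
      i, x$median_diameter[i], x$geometric_sd[i], x$weight[i]
    ))
  }
  cat(sprintf(
    "  cutoff: %s, concentration: %.3g /ml\n",
    if (is.null(x$extrusion_cutoff)) "none" else paste0(x$extrusion_cutoff, " nm"),
    x$concentration
  ))
  invisible(x)
}

#' Draw particle diameters from a population
#'
#' Samples the lognormal mixture and rejection-resamples any draw above the
#' extrusion cutoff, giving a hard upper truncation with the sub-cutoff
#' shape unchanged.
#'
#' @param spec A [population_spec()].
#' @param n Number of particles to draw.
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector of `n` diameters in nm.
#' @export
sample_population <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "population_spec")) {
    abort("`spec` must be created with population_spec().")
  }
  check_scalar_positive(n, "n")
  n <- as.integer(n)
  with_seed(seed, {
    comp <- sample.int(length(spec$weight), n, replace = TRUE, prob = spec$weight)
    d <- rlnorm(n,
      meanlog = log(spec$median_diameter)[comp],
      sdlog = log(spec$geometric_sd)[comp]
    )
    if (!is.null(spec$extrusion_cutoff)) {
      bad <- which(d > spec$extrusion_cutoff)
      while (length(bad)) {
        comp_b <- sample.int(length(spec$weight), length(bad),
          replace = TRUE, prob = spec$weight
        )
        d[bad] <- rlnorm(length(bad),
          meanlog = log(spec$median_diameter)[comp_b],
          sdlog = log(spec$geometric_sd)[comp_b]
        )
        bad <- bad[d[bad] > spec$extrusion_cutoff]
      }
    }
    d
  })
}
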