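#' Curvature-dependent protein binding model
#'
#' Binding of a fluorescent protein to a liposome is modelled as a Bernoulli
#' event whose probability depends on liposome diameter through a logistic
#' curve in log-diameter. Three qualitative regimes cover the assay's
#' expected outcomes:
#' \describe{
#'   \item{`high_curvature`}{probability decreases with diameter from
#'     `max_prob` towards `baseline_prob` (preference for small, highly
#'     curved liposomes, as for an N-BAR domain);}
#'   \item{`insensitive`}{constant `max_prob` at every size (an F-BAR-like
#'     binder with no preference);}
#'   \item{`low_curvature`}{probability increases with diameter (an
#'     I-BAR-like preference for the largest, flattest liposomes).}
#' }
#' Protein concentration is not modelled kinetically; `max_prob` is its
#' proxy (the assay operates at a fixed, nanomolar concentration).
#'
#' @param kind One of `"high_curvature"`, `"insensitive"`, `"low_curvature"`.
#' @param midpoint Diameter in nm at which the probability is halfway
#'   between `baseline_prob` and `max_prob`.
#' @param steepness Unitless logistic steepness in log-diameter.
#' @param max_prob Plateau binding probability.
#' @param baseline_prob Residual binding probability at disfavoured sizes.
#' @return An object of class `binding_model`.
#' @export
#' @examples
#' binding_model("high_curvature", midpoint = 150)
binding_model <- function(kind = c("high_curvature", "insensitive", "low_curvature"),
                          midpoint = 150, steepness = 10,
                          max_prob = 0.95, baseline_prob = 0.02) {
  kind <- match.arg(kind)
  check_scalar_positive(midpoint, "midpoint")
  check_scalar_positive(steepness, "steepness")
  check_prob(max_prob, "max_prob")
  check_prob(baseline_prob, "baseline_prob")
  if (baseline_prob > max_prob) {
    abort("`baseline_prob` must not exceed `max_prob`.")
  }
  structure(
    list(
      kind = kind, midpoint = midpoint, steepness = steepness,
      max_prob = max_prob, baseline_prob = baseline_prob
    ),
    class = "binding_model"
  )
}

#' Binding probability as a function of liposome diameter
#'
#' @param diameter Diameter(s) in nm.
#' @param model A [binding_model()].
#' @return Binding probability in \[0, 1\], vectorised over `diameter`.
#' @export
binding_probability <- function(diameter, model) {
  if (!inherits(model, "binding_model")) {
    abort("`model` must be created with binding_model().")
  }
  if (any(diameter <= 0)) abort("`diameter` must be positive.")
  if (model$kind == "insensitive") {
    return(rep(model$max_prob, length(diameter)))
  }
  sign <- if (model$kind == "high_curvature") -1 else 1
  z <- sign * model$steepness * log(diameter / model$midpoint)
  model$baseline_prob + (model$max_prob - model$baseline_prob) * stats::plogis(z)
}

#' Bernoulli labelling of particles by a binding model
#'
#' Simulates the incubation of non-fluorescent liposomes with a fluorescent
#' protein: each particle independently acquires a fluorescent label with
#' probability [binding_probability()] at its diameter.
#'
#' @param diameters Particle diameters in nm.
#' @param model A [binding_model()].
#' @param seed Optional integer seed.
#' @return Logical vector of labelled flags.
#' @export
label_by_binding <- function(diameters, model, seed = NULL) {
  p <- binding_probability(diameters, model)
  with_seed(seed, runif(length(diameters)) < p)
}
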