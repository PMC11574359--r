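#' Vesiculation model
#'
#' Dose-dependent fragmentation of liposomes into smaller vesicles by
#' membrane-inserting protein domains (ENTH/ANTH-like activity). The
#' fraction of liposomes processed at a given dose follows a Hill curve,
#' and a processed parent is replaced by daughters whose diameters are
#' drawn from a lognormal, subject to exact conservation of membrane area
#' (sum of d^2): lipid is neither created nor destroyed by vesiculation.
#'
#' @param max_fraction Maximum fraction of liposomes processed at
#'   saturating dose (a proxy for the protein's vesiculation efficiency).
#' @param half_dose Dose at half-maximal processing, in uM.
#' @param hill Hill coefficient (unitless).
#' @param daughter_median Median daughter diameter in nm.
#' @param daughter_gsd Geometric SD of daughter diameters (> 1).
#' @param dose Protein dose in uM (>= 0).
#' @param min_daughter Smallest allowed daughter diameter in nm; a terminal
#'   area remainder smaller than this folds into the previous daughter.
#' @return An object of class `vesiculation_model`.
#' @export
#' @examples
#' vesiculation_model(max_fraction = 0.8, dose = 2)
vesiculation_model <- function(max_fraction = 0.8, half_dose = 1, hill = 1.5,
                               daughter_median = 70, daughter_gsd = 1.25,
                               dose = 0, min_daughter = 20) {
  check_prob(max_fraction, "max_fraction")
  check_scalar_positive(half_dose, "half_dose")
  check_scalar_positive(hill, "hill")
  check_scalar_positive(daughter_median, "daughter_median")
  if (daughter_gsd <= 1) abort("`daughter_gsd` must be > 1.")
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0) {
    abort("`dose` must be a single non-negative number (uM).")
  }
  check_scalar_positive(min_daughter, "min_daughter")
  structure(
    list(
      max_fraction = max_fraction, half_dose = half_dose, hill = hill,
      daughter_median = daughter_median, daughter_gsd = daughter_gsd,
      dose = dose, min_daughter = min_daughter
    ),
    class = "vesiculation_model"
  )
}

#' Fraction of liposomes processed at a dose
#'
#' Hill curve `max_fraction * dose^h / (dose^h + half_dose^h)`.
#'
#' @param model A [vesiculation_model()].
#' @param dose Dose(s) in uM; defaults to the model's own dose.
#' @return Processing probability.
#' @export
vesiculation_fraction <- function(model, dose = model$dose) {
  if (!inherits(model, "vesiculation_model")) {
    abort("`model` must be created with vesiculation_model().")
  }
  ifelse(dose <= 0, 0,
    model$max_fraction * dose^model$hill /
      (dose^model$hill + model$half_dose^model$hill)
  )
}

#' A simulated particle sample
#'
#' Particles (diameter + fluorescent-label flag) together with the sample
#' volume they occupy, the unit the vesiculation stage operates on.
#'
#' @param diameter Particle diameters in nm.
#' @param labelled Logical label flags (default all `TRUE`: vesiculation
#'   experiments use fluorescent liposomes).
#' @param volume Sample volume in ml.
#' @return A tibble of class `simulated_sample` with columns `diameter`
#'   and `labelled` and a `volume` attribute.
#' @export
simulated_sample <- function(diameter, labelled = TRUE, volume = 1e-5) {
  if (any(diameter <= 0)) abort("diameters must be positive.")
  check_scalar_positive(volume, "volume")
  labelled <- rep_len(as.logical(labelled), length(diameter))
  out <- tibble(diameter = as.numeric(diameter), labelled = labelled)
  structure(out, volume = volume, class = c("simulated_sample", class(out)))
}

# Split one parent diameter into daughters conserving total d^2.
# Returns the parent unchanged (and attribute skipped=TRUE) when the
# daughter scale is not below the parent.
split_parent <- function(d_parent, model) {
  if (model$daughter_median >= d_parent) {
    return(structure(d_parent, skipped = TRUE))
  }
  area <- d_parent^2
  daughters <- numeric(0)
  used <- 0
  repeat {
    d <- rlnorm(1,
      meanlog = log(model$daughter_median),
      sdlog = log(model$daughter_gsd)
    )
    if (used + d^2 < area) {
      daughters <- c(daughters, d)
      used <- used + d^2
    } else {
      rem <- sqrt(area - used)
      if (rem >= model$min_daughter || length(daughters) == 0L) {
        daughters <- c(daughters, rem)
      } else {
        k <- length(daughters)
        daughters[k] <- sqrt(daughters[k]^2 + rem^2)
      }
      break
    }
  }
  daughters
}

#' Apply dose-dependent vesiculation to a sample
#'
#' Each particle is processed with the Hill-curve probability of
#' [vesiculation_fraction()]. A processed parent of diameter `d` is
#' replaced by daughters drawn from the model's lognormal until its
#' membrane area is exhausted; the last daughter takes the exact area
#' remainder (or folds into the previous daughter if below
#' `min_daughter`), so the total membrane area `sum(d^2)` of the sample is
#' conserved exactly. Daughters inherit the parent's label. Parents whose
#' diameter does not exceed the daughter scale pass through unchanged and
#' are counted in a message.
#'
#' @param sample A [simulated_sample()].
#' @param model A [vesiculation_model()] (its `dose` field sets the dose).
#' @param seed Optional integer seed.
#' @return A new `simulated_sample` with the same volume.
#' @export
vesiculate <- function(sample, model, seed = NULL) {
  if (!inherits(sample, "simulated_sample")) {
    abort("`sample` must be created with simulated_sample().")
  }
  if (!inherits(model, "vesiculation_model")) {
    abort("`model` must be created with vesiculation_model().")
  }
  p <- vesiculation_fraction(model)
  if (p == 0 || nrow(sample) == 0L) {
    return(sample)
  }
  volume <- attr(sample, "volume")
  with_seed(seed, {
    processed <- runif(nrow(sample)) < p
    n_skipped <- 0L
    pieces <- lapply(seq_len(nrow(sample)), function(i) {
      if (!processed[i]) {
        return(sample$diameter[i])
      }
      d <- split_parent(sample$diameter[i], model)
      if (isTRUE(attr(d, "skipped"))) n_skipped <<- n_skipped + 1L
      as.numeric(d)
    })
    if (n_skipped > 0L) {
      inform(sprintf(
        "%d processed parent(s) not larger than the daughter scale passed through.",
        n_skipped
      ))
    }
    counts <- lengths(pieces)
    simulated_sample(
      diameter = unlist(pieces, use.names = FALSE),
      labelled = rep(sample$labelled, counts),
      volume = volume
    )
  })
}
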