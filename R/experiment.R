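#' Simulate a complete two-channel tracking experiment
#'
#' Composes the simulator stages into the full assay pipeline: draw a
#' liposome population, label particles by curvature-dependent protein
#' binding, determine which particles are observed in each detection
#' channel, and generate a Brownian track for every observed particle.
#' The diffraction channel plays the role of the total-population
#' measurement; the fluorescence channel sees the protein-bound
#' subpopulation only.
#'
#' All randomness derives from the single `seed` through per-stage
#' substreams ([derive_seed()]), so the same seed always reproduces the
#' same tracks.
#'
#' @param spec A [population_spec()].
#' @param binding A [binding_model()].
#' @param detection A [detection_model()].
#' @param medium A [medium_conditions()] object.
#' @param acq An [acquisition_config()] object.
#' @param n_particles Number of particles in the sample.
#' @param seed Integer master seed.
#' @return A list with elements
#'   \describe{
#'     \item{`tracks`}{track table for both channels (fluorescence track
#'       ids continue after diffraction ids);}
#'     \item{`truth`}{tibble of ground truth per sampled particle:
#'       `particle`, `diameter`, `labelled`, and per-channel observation
#'       flags `seen_diffraction`, `seen_fluorescence`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_experiment(
#'   population_spec(220, 1.5, extrusion_cutoff = 800),
#'   binding_model("high_curvature"),
#'   n_particles = 50, seed = 1
#' )
#' dplyr::count(sim$tracks, channel)
simulate_experiment <- function(spec, binding,
                                detection = detection_model(),
                                medium = medium_conditions(),
                                acq = acquisition_config(),
                                n_particles = 3000, seed = 1) {
  check_scalar_positive(n_particles, "n_particles")
  n_particles <- as.integer(n_particles)
  d <- sample_population(spec, n_particles, seed = derive_seed(seed, "population"))
  lab <- label_by_binding(d, binding, seed = derive_seed(seed, "binding"))
  particles <- tibble(particle = seq_len(n_particles), diameter = d, labelled = lab)
  seen_diff <- apply_detection(particles, detection, "diffraction",
    seed = derive_seed(seed, "detect_diffraction")
  )
  seen_fluo <- apply_detection(particles, detection, "fluorescence",
    seed = derive_seed(seed, "detect_fluorescence")
  )
  trk_diff <- simulate_tracks(seen_diff$diameter, medium, acq,
    seed = derive_seed(seed, "tracks_diffraction"), channel = "diffraction"
  )
  trk_fluo <- simulate_tracks(seen_fluo$diameter, medium, acq,
    seed = derive_seed(seed, "tracks_fluorescence"),
    channel = "fluorescence",
    first_id = if (nrow(trk_diff)) max(trk_diff$track_id) + 1L else 1L
  )
  truth <- particles |>
    dplyr::mutate(
      seen_diffraction = .data$particle %in% seen_diff$particle,
      seen_fluorescence = .data$particle %in% seen_fluo$particle
    )
  list(tracks = dplyr::bind_rows(trk_diff, trk_fluo), truth = truth)
}
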