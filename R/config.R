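# Run configuration.
#
# A flat YAML file with one section per parameter block. Defaults encode
# the standard acquisition (120 s movies at 25 fps) and analysis settings
# (5-nm bins, 7-point display smoothing, 10-step track filter, alpha
# 0.05, 5-nm minimum mode shift).

#' Default run configuration
#'
#' @return A nested list of class `run_config` with sections `medium`,
#'   `acquisition`, `analysis`, `population`, `binding`, `detection`,
#'   `vesiculation` and a master `seed`.
#' @export
#' @examples
#' cfg <- default_run_config()
#' cfg$acquisition$frame_rate
default_run_config <- function() {
  structure(
    list(
      seed = 1L,
      medium = list(temperature = 298.15, viscosity = 8.9e-4),
      acquisition = list(
        frame_rate = 25, duration = 120,
        mean_track_length = 50, observed_volume = 1e-5
      ),
      analysis = list(
        bin_width = 5, smooth_window = 7, min_steps = 10,
        alpha = 0.05, min_shift = 5
      ),
      population = list(
        median_diameter = 220, geometric_sd = 1.4, weight = 1,
        extrusion_cutoff = 800, concentration = 3e8
      ),
      binding = list(
        kind = "high_curvature", midpoint = 150, steepness = 10,
        max_prob = 0.95, baseline_prob = 0.02
      ),
      detection = list(
        diffraction_midpoint = 90, diffraction_steepness = 6,
        fluorescence_prob = 0.95
      ),
      vesiculation = list(
        max_fraction = 0.8, half_dose = 1, hill = 1.5,
        daughter_median = 70, daughter_gsd = 1.25, min_daughter = 20,
        doses = c(0, 0.5, 1, 2, 4)
      ),
      simulate = list(n_particles = 6000, n_replicates = 3)
    ),
    class = "run_config"
  )
}

#' Read a run configuration file
#'
#' Reads a YAML configuration and merges it over the defaults, so a file
#' only needs to state the parameters it changes. The file's MD5 hash is
#' attached for provenance (output files embed it in their metadata).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `run_config` list with attributes `config_hash` and `path`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) {
    return(structure(cfg, config_hash = "defaults", path = NA_character_))
  }
  if (!file.exists(path)) {
    abort(sprintf("config file '%s' not found.", path))
  }
  user <- yaml::read_yaml(path)
  if (!is.list(user)) abort(sprintf("'%s' is not a YAML mapping.", path))
  known <- names(unclass(cfg))
  unknown <- setdiff(names(user), known)
  if (length(unknown)) {
    abort(sprintf(
      "unknown config section(s) in '%s': %s.",
      path, paste(unknown, collapse = ", ")
    ))
  }
  merged <- modifyList(unclass(cfg), user)
  structure(merged,
    class = "run_config",
    config_hash = unname(tools::md5sum(path)), path = path
  )
}

# Constructors from config sections -------------------------------------

config_medium <- function(cfg) {
  medium_conditions(cfg$medium$temperature, cfg$medium$viscosity)
}

config_acquisition <- function(cfg) {
  acquisition_config(
    frame_rate = cfg$acquisition$frame_rate,
    duration = cfg$acquisition$duration,
    mean_track_length = cfg$acquisition$mean_track_length,
    observed_volume = cfg$acquisition$observed_volume
  )
}

config_population <- function(cfg) {
  p <- cfg$population
  population_spec(
    median_diameter = p$median_diameter, geometric_sd = p$geometric_sd,
    weight = p$weight,
    extrusion_cutoff = p$extrusion_cutoff,
    concentration = p$concentration
  )
}

config_binding <- function(cfg) {
  b <- cfg$binding
  binding_model(
    kind = b$kind, midpoint = b$midpoint, steepness = b$steepness,
    max_prob = b$max_prob, baseline_prob = b$baseline_prob
  )
}

config_detection <- function(cfg) {
  d <- cfg$detection
  detection_model(
    diffraction_midpoint = d$diffraction_midpoint,
    diffraction_steepness = d$diffraction_steepness,
    fluorescence_prob = d$fluorescence_prob
  )
}

config_vesiculation <- function(cfg, dose = 0) {
  v <- cfg$vesiculation
  vesiculation_model(
    max_fraction = v$max_fraction, half_dose = v$half_dose, hill = v$hill,
    daughter_median = v$daughter_median, daughter_gsd = v$daughter_gsd,
    dose = dose, min_daughter = v$min_daughter
  )
}
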