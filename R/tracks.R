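# Trajectory tables and the per-track diffusion estimator.
#
# A track table has one row per localisation with columns:
#   track_id, frame, x_um, y_um, channel
# Frames are consecutive integers within a track; `channel` is
# "diffraction" or "fluorescence". The frame interval (seconds) is an
# acquisition parameter carried alongside the table, not a column.

track_channels <- c("diffraction", "fluorescence")

check_tracks <- function(tracks) {
  if (!is.data.frame(tracks)) {
    abort("`tracks` must be a data frame of localisations.")
  }
  need <- c("track_id", "frame", "x_um", "y_um", "channel")
  missing <- setdiff(need, names(tracks))
  if (length(missing)) {
    abort(paste0(
      "`tracks` is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  invisible(tracks)
}

#' Lag-1 MSD diffusion estimator for a single trajectory
#'
#' Estimates the diffusion coefficient of one particle from its 2D positions
#' as the mean squared per-frame displacement divided by `4 * frame_interval`
#' (for 2D Brownian motion, MSD(tau) = 4 D tau). The single-lag estimator is
#' unbiased for pure Brownian motion and avoids the correlated-lag weighting
#' issues of multi-lag MSD fits.
#'
#' @param x,y Numeric position vectors in micrometres, one entry per
#'   consecutive frame. At least 2 positions.
#' @param frame_interval Time between frames in seconds.
#' @return Estimated diffusion coefficient in um^2/s (>= 0).
#' @export
#' @examples
#' lag1_diffusion(c(0, 2), c(0, 0), frame_interval = 0.04) # 25 um^2/s
lag1_diffusion <- function(x, y, frame_interval) {
  if (length(x) < 2L || length(y) != length(x)) {
    abort("a track needs at least 2 positions with equal-length x and y.")
  }
  check_scalar_positive(frame_interval, "frame_interval")
  mean(diff(x)^2 + diff(y)^2) / (4 * frame_interval)
}

#' Per-track diffusion coefficients from a track table
#'
#' Applies [lag1_diffusion()] to every track in a localisation table.
#'
#' @param tracks Track table (see [read_tracks()] for the schema).
#' @param frame_interval Time between frames in seconds (default 1/25 s,
#'   i.e. 25 fps acquisition).
#' @return A tibble with one row per track: `track_id`, `channel`,
#'   `n_steps`, `diffusion_coeff` (um^2/s).
#' @export
estimate_diffusion <- function(tracks, frame_interval = 1 / 25) {
  check_tracks(tracks)
  check_scalar_positive(frame_interval, "frame_interval")
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id, .data$channel) |>
    dplyr::summarise(
      n_steps = dplyr::n() - 1L,
      diffusion_coeff = if (dplyr::n() >= 2L) {
        mean(diff(.data$x_um)^2 + diff(.data$y_um)^2) / (4 * frame_interval)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Remove common drift from an ensemble of tracks
#'
#' Subtracts the per-frame ensemble-mean displacement from every step, so a
#' uniform flow (e.g. from a syringe pump) shared by all particles cancels
#' while each particle's Brownian component is preserved. After correction
#' the ensemble-mean step is zero at every frame transition. Correction is
#' opt-in: instrument software normally handles flow itself.
#'
#' @param tracks Track table.
#' @return The corrected track table (same shape). A single track is
#'   returned unchanged with a warning, since drift cannot be separated from
#'   diffusion with one particle.
#' @export
drift_correct <- function(tracks) {
  check_tracks(tracks)
  if (nrow(tracks) == 0L) {
    return(as_tibble(tracks))
  }
  tracks <- dplyr::arrange(as_tibble(tracks), .data$track_id, .data$frame)
  if (dplyr::n_distinct(tracks$track_id) < 2L) {
    warn("only one track supplied; drift correction skipped.")
    return(tracks)
  }
  steps <- tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(dx = c(NA, diff(.data$x_um)), dy = c(NA, diff(.data$y_um))) |>
    dplyr::ungroup()
  # mean displacement for each frame transition (frame-1 -> frame)
  drift <- steps |>
    dplyr::filter(!is.na(.data$dx)) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      mdx = mean(.data$dx), mdy = mean(.data$dy), .groups = "drop"
    )
  steps |>
    dplyr::left_join(drift, by = "frame") |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      x_um = .data$x_um[1] + cumsum(dplyr::coalesce(.data$dx - .data$mdx, 0)),
      y_um = .data$y_um[1] + cumsum(dplyr::coalesce(.data$dy - .data$mdy, 0))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("track_id", "frame", "x_um", "y_um", "channel")))
}

#' Hydrodynamic size estimates for every track
#'
#' The workhorse of the sizing pipeline: estimates each track's diffusion
#' coefficient by lag-1 MSD, filters out tracks shorter than `min_steps`
#' steps, and converts the survivors to hydrodynamic diameters with the
#' Stokes-Einstein relation. Tracks with zero estimated diffusion (a
#' perfectly stationary trajectory) have no finite diameter and are dropped
#' with a message.
#'
#' @param tracks Track table.
#' @param medium A [medium_conditions()] object.
#' @param frame_interval Time between frames in seconds.
#' @param min_steps Minimum number of displacement steps for a track to be
#'   sized (default 10).
#' @return A tibble of size estimates: `track_id`, `channel`, `n_steps`,
#'   `diffusion_coeff` (um^2/s), `diameter` (nm). Empty input gives an empty
#'   tibble.
#' @export
size_tracks <- function(tracks, medium = medium_conditions(),
                        frame_interval = 1 / 25, min_steps = 10) {
  check_medium(medium)
  est <- estimate_diffusion(tracks, frame_interval) |>
    dplyr::filter(.data$n_steps >= min_steps)
  n_zero <- sum(est$diffusion_coeff <= 0, na.rm = TRUE)
  if (n_zero > 0) {
    inform(sprintf("dropped %d track(s) with zero estimated diffusion.", n_zero))
  }
  est |>
    dplyr::filter(.data$diffusion_coeff > 0) |>
    dplyr::mutate(diameter = stokes_einstein_diameter(.data$diffusion_coeff, medium))
}
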