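#' Acquisition configuration
#'
#' Video-acquisition parameters of a tracking run. Defaults correspond to
#' short movies of 120 s recorded at 25 fps. Track lengths are geometric
#' (particles diffuse out of the thin illuminated volume at a constant
#' per-frame hazard) with the given mean, capped at the movie length.
#'
#' @param frame_rate Frames per second. Default 25.
#' @param duration Movie duration in seconds. Default 120.
#' @param mean_track_length Mean track length in frames. Default 50.
#' @param observed_volume Effective observed sample volume in ml, used to
#'   convert particle counts to concentrations. Default 1e-5 ml, placing a
#'   typical 3000-8000-particle run at a few 1e8 particles/ml.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 25, duration = 120,
                               mean_track_length = 50,
                               observed_volume = 1e-5) {
  check_scalar_positive(frame_rate, "frame_rate")
  check_scalar_positive(duration, "duration")
  check_scalar_positive(mean_track_length, "mean_track_length")
  check_scalar_positive(observed_volume, "observed_volume")
  structure(
    list(
      frame_rate = frame_rate, duration = duration,
      mean_track_length = mean_track_length,
      observed_volume = observed_volume
    ),
    class = "acquisition_config"
  )
}

check_acquisition <- function(acq) {
  if (!inherits(acq, "acquisition_config")) {
    abort("`acq` must be created with acquisition_config().")
  }
  invisible(acq)
}

#' Simulate Brownian tracks for a set of particles
#'
#' Generates 2D-projected Brownian trajectories: per-axis steps are i.i.d.
#' Gaussian with variance `2 * D * dt`, where each particle's diffusion
#' coefficient comes from the forward Stokes-Einstein relation at its
#' diameter. Track lengths (in positions) are drawn geometric with mean
#' `acq$mean_track_length`, bounded to \[2, duration * frame_rate\], unless
#' a fixed `n_steps` is requested.
#'
#' @param diameters Particle diameters in nm (one track per particle).
#' @param medium A [medium_conditions()] object.
#' @param acq An [acquisition_config()] object.
#' @param seed Optional integer seed.
#' @param n_steps If non-NULL, every track gets exactly this many
#'   displacement steps instead of a geometric length.
#' @param channel Channel tag stored with the tracks.
#' @param first_id Integer id of the first track (ids are consecutive).
#' @return A track table (tibble): `track_id`, `frame`, `x_um`, `y_um`,
#'   `channel`.
#' @export
#' @examples
#' acq <- acquisition_config()
#' trk <- simulate_tracks(c(100, 216), acq = acq, seed = 1)
#' head(trk)
simulate_tracks <- function(diameters, medium = medium_conditions(),
                            acq = acquisition_config(), seed = NULL,
                            n_steps = NULL, channel = "diffraction",
                            first_id = 1L) {
  check_medium(medium)
  check_acquisition(acq)
  if (!channel %in% track_channels) {
    abort('`channel` must be "diffraction" or "fluorescence".')
  }
  n <- length(diameters)
  if (n == 0L) {
    return(tibble(
      track_id = integer(), frame = integer(),
      x_um = numeric(), y_um = numeric(), channel = character()
    ))
  }
  dt <- 1 / acq$frame_rate
  D <- diameter_to_diffusion(diameters, medium)
  sd_step <- sqrt(2 * D * dt)
  max_pos <- max(2L, as.integer(floor(acq$duration * acq$frame_rate)))
  with_seed(seed, {
    n_positions <- if (is.null(n_steps)) {
      pmin(pmax(1L + rgeom(n, 1 / acq$mean_track_length), 2L), max_pos)
    } else {
      rep(as.integer(n_steps) + 1L, n)
    }
    steps <- n_positions - 1L
    total <- sum(steps)
    sd_rep <- rep(sd_step, steps)
    dx <- rnorm(total, sd = sd_rep)
    dy <- rnorm(total, sd = sd_rep)
    csx <- cumsum(dx)
    csy <- cumsum(dy)
    last <- cumsum(steps)
    # interleave a synthetic first "step" per track that cancels the
    # running sum of all previous tracks, so one global cumsum yields
    # per-track positions starting at the origin
    n_rows <- sum(n_positions)
    starts <- cumsum(c(1L, head(n_positions, -1L)))
    fx <- numeric(n_rows)
    fy <- numeric(n_rows)
    fx[-starts] <- dx
    fy[-starts] <- dy
    # a track's final position is csx[last_i] - csx[last_(i-1)]; the next
    # track's synthetic first step must cancel exactly that
    end_x <- diff(c(0, csx[last]))
    end_y <- diff(c(0, csy[last]))
    fx[starts] <- c(0, -head(end_x, -1L))
    fy[starts] <- c(0, -head(end_y, -1L))
    tibble(
      track_id = rep(seq_len(n) + (first_id - 1L), n_positions),
      frame = sequence(n_positions),
      x_um = cumsum(fx),
      y_um = cumsum(fy),
      channel = rep(channel, n_rows)
    )
  })
}

#' Simulate one Brownian track
#'
#' Convenience wrapper around [simulate_tracks()] for a single particle.
#'
#' @inheritParams simulate_tracks
#' @param diameter Particle diameter in nm.
#' @param track_id Track id assigned to the output.
#' @return A track table with one track.
#' @export
simulate_track <- function(diameter, medium = medium_conditions(),
                           acq = acquisition_config(), seed = NULL,
                           n_steps = NULL, channel = "diffraction",
                           track_id = 1L) {
  check_scalar_positive(diameter, "diameter")
  simulate_tracks(diameter, medium, acq,
    seed = seed, n_steps = n_steps,
    channel = channel, first_id = as.integer(track_id)
  )
}
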