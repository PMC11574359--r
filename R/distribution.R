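# Binned size-concentration distributions.
#
# The canonical representation of a sizing run: particle concentration
# (particles/ml) in half-open diameter bins [w*k, w*(k+1)) of width w
# (default 5 nm), so that bin centres sit at w*k + w/2 -- with 5-nm bins
# one bin is centred at 82.5 nm, the marker bin of the vesiculation assay.

new_size_distribution <- function(bin_centre, concentration, bin_width = 5,
                                  channel = NA_character_, n_particles = NA_integer_,
                                  observed_volume = NA_real_, label = NA_character_) {
  out <- tibble(bin_centre = bin_centre, concentration = concentration)
  structure(
    out,
    bin_width = bin_width, channel = channel,
    n_particles = n_particles, observed_volume = observed_volume,
    label = label,
    class = c("size_distribution", class(out))
  )
}

# carry attributes from `template` onto a rebuilt tibble
rebuild_distribution <- function(out, template, ...) {
  args <- modifyList(
    list(
      bin_width = attr(template, "bin_width"),
      channel = attr(template, "channel"),
      n_particles = attr(template, "n_particles"),
      observed_volume = attr(template, "observed_volume"),
      label = attr(template, "label")
    ),
    list(...)
  )
  do.call(new_size_distribution, c(
    list(bin_centre = out$bin_centre, concentration = out$concentration), args
  ))
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "<size_distribution> %d bins of %g nm, channel %s, %s particles\n",
    nrow(x), attr(x, "bin_width"), attr(x, "channel"),
    format(attr(x, "n_particles"))
  ))
  NextMethod()
}

check_distribution <- function(dist, name = "dist") {
  if (!inherits(dist, "size_distribution")) {
    abort(sprintf("`%s` must be a size_distribution (see bin_sizes()).", name))
  }
  invisible(dist)
}

check_same_binning <- function(a, b) {
  if (!isTRUE(all.equal(attr(a, "bin_width"), attr(b, "bin_width"))) ||
    nrow(a) != nrow(b) || !isTRUE(all.equal(a$bin_centre, b$bin_centre))) {
    abort("distributions are on different bin grids; align them first (see align_distributions()).")
  }
  invisible(TRUE)
}

#' Bin size estimates into a concentration distribution
#'
#' Counts diameters into half-open bins `[w*k, w*(k+1))` and divides by the
#' observed sample volume, giving particle concentration per bin. Leading
#' and trailing empty bins are trimmed; interior empty bins are kept.
#'
#' @param estimates A tibble of size estimates with a `diameter` column
#'   (nm), e.g. from [size_tracks()], or a bare numeric vector of
#'   diameters.
#' @param observed_volume Observed sample volume in ml.
#' @param bin_width Bin width in nm (default 5).
#' @param channel,label Optional metadata stored on the result.
#' @return A `size_distribution` tibble with columns `bin_centre` (nm) and
#'   `concentration` (particles/ml).
#' @export
#' @examples
#' bin_sizes(c(82, 83, 101), observed_volume = 1e-6)
bin_sizes <- function(estimates, observed_volume, bin_width = 5,
                      channel = NA_character_, label = NA_character_) {
  check_scalar_positive(observed_volume, "observed_volume")
  check_scalar_positive(bin_width, "bin_width")
  diameters <- if (is.data.frame(estimates)) {
    if (!"diameter" %in% names(estimates)) {
      abort("`estimates` needs a `diameter` column.")
    }
    if (is.na(channel) && "channel" %in% names(estimates) &&
      nrow(estimates) > 0L && dplyr::n_distinct(estimates$channel) == 1L) {
      channel <- estimates$channel[1]
    }
    estimates$diameter
  } else {
    as.numeric(estimates)
  }
  if (length(diameters) == 0L) {
    return(new_size_distribution(
      numeric(0), numeric(0),
      bin_width = bin_width,
      channel = channel, n_particles = 0L,
      observed_volume = observed_volume, label = label
    ))
  }
  if (any(diameters <= 0)) abort("diameters must be positive.")
  k <- floor(diameters / bin_width)
  kk <- seq(min(k), max(k))
  counts <- tabulate(k - min(k) + 1L, nbins = length(kk))
  new_size_distribution(
    bin_centre = kk * bin_width + bin_width / 2,
    concentration = counts / observed_volume,
    bin_width = bin_width, channel = channel,
    n_particles = length(diameters),
    observed_volume = observed_volume, label = label
  )
}

#' Moving-average smoothing of a distribution
#'
#' Centred moving average of the given odd window (default 7 bins,
#' the conventional display smoothing for these curves); at the edges the
#' window truncates to the available bins. Smoothing is intended for
#' display only -- mode and box statistics are computed on raw binned
#' data.
#'
#' @param dist A `size_distribution`.
#' @param window Odd window length in bins; `window = 1` is the identity.
#' @return A smoothed `size_distribution`.
#' @export
smooth_distribution <- function(dist, window = 7) {
  check_distribution(dist)
  if (length(window) != 1L || window < 1 || window %% 2 == 0) {
    abort("`window` must be a single odd positive integer.")
  }
  n <- nrow(dist)
  if (n == 0L || window == 1) {
    return(dist)
  }
  h <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    mean(dist$concentration[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  out <- tibble(bin_centre = dist$bin_centre, concentration = sm)
  rebuild_distribution(out, dist)
}

#' Concentration-weighted mean diameter
#'
#' @param dist A non-empty `size_distribution`.
#' @return Mean diameter in nm.
#' @export
mean_size <- function(dist) {
  check_distribution(dist)
  tot <- sum(dist$concentration)
  if (nrow(dist) == 0L || tot <= 0) abort("distribution has no mass.")
  sum(dist$bin_centre * dist$concentration) / tot
}

#' Total particle concentration
#'
#' @param dist A `size_distribution`.
#' @return Summed concentration over all bins, particles/ml.
#' @export
total_concentration <- function(dist) {
  check_distribution(dist)
  sum(dist$concentration)
}

#' Concentration in one bin
#'
#' Exact lookup of a bin centre on the distribution's grid (0 if the bin
#' lies outside the distribution's range). An off-grid centre is an error.
#'
#' @param dist A `size_distribution`.
#' @param centre Bin centre in nm, e.g. 82.5 for the vesiculation marker
#'   bin with 5-nm bins.
#' @return Concentration in particles/ml.
#' @export
bin_concentration_at <- function(dist, centre) {
  check_distribution(dist)
  w <- attr(dist, "bin_width")
  if (!isTRUE(all.equal((centre - w / 2) %% w, 0)) &&
    !isTRUE(all.equal((centre - w / 2) %% w, w))) {
    abort(sprintf("`centre` %g nm is not on the %g-nm bin grid.", centre, w))
  }
  hit <- which(abs(dist$bin_centre - centre) < 1e-9)
  if (length(hit) == 0L) {
    return(0)
  }
  dist$concentration[hit]
}

#' Pad two distributions onto a common bin grid
#'
#' Extends both distributions with zero-concentration bins so they share
#' the union of their grids, a prerequisite for bin-wise operations such
#' as [compute_cf()].
#'
#' @param a,b `size_distribution`s with equal bin width.
#' @return A list with elements `a` and `b` on the common grid.
#' @export
align_distributions <- function(a, b) {
  check_distribution(a, "a")
  check_distribution(b, "b")
  w <- attr(a, "bin_width")
  if (!isTRUE(all.equal(w, attr(b, "bin_width")))) {
    abort("bin widths differ.")
  }
  centres <- range(c(a$bin_centre, b$bin_centre))
  grid <- seq(centres[1], centres[2], by = w)
  pad <- function(d) {
    conc <- rep(0, length(grid))
    idx <- round((d$bin_centre - grid[1]) / w) + 1L
    conc[idx] <- d$concentration
    rebuild_distribution(tibble(bin_centre = grid, concentration = conc), d)
  }
  list(a = pad(a), b = pad(b))
}
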