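#' Mode-centred box statistics of a size distribution
#'
#' Summarises a distribution the way the assay's box plots do: the middle
#' line is the mode (centre of the maximum-concentration bin; ties go to
#' the smallest centre) and each box boundary encloses 50% of the
#' concentration mass lying on that side of the mode bin. Boundaries are
#' located by linear interpolation on the outward cumulative concentration
#' from the mode bin's edge, which keeps them continuous despite the 5-nm
#' bin granularity. A side with no mass collapses its boundary onto the
#' mode. Statistics are computed on raw binned data; smoothing is a
#' display step only.
#'
#' @param dist A non-empty `size_distribution`.
#' @return A one-row tibble of class `box_stats`: `mode`, `lower`,
#'   `upper` (nm), with `lower <= mode <= upper`.
#' @export
#' @examples
#' d <- bin_sizes(rep(c(77, 82, 87, 92), c(1, 4, 1, 3)) + 0.5, 1e-6)
#' box_stats(d)
box_stats <- function(dist) {
  check_distribution(dist)
  if (nrow(dist) == 0L || sum(dist$concentration) <= 0) {
    abort("cannot compute box statistics of an empty distribution.")
  }
  w <- attr(dist, "bin_width")
  conc <- dist$concentration
  centre <- dist$bin_centre
  m <- which.max(conc) # ties: first = smallest centre
  mode <- centre[m]

  outward_boundary <- function(side_conc, edge, direction) {
    # side_conc ordered outward from the mode bin's edge; direction -1
    # walks down-diameter, +1 up-diameter
    mass <- sum(side_conc)
    if (mass <= 0) {
      return(mode)
    }
    target <- mass / 2
    cum <- cumsum(side_conc)
    j <- which(cum >= target)[1]
    prev <- if (j > 1) cum[j - 1] else 0
    frac <- (target - prev) / side_conc[j]
    edge + direction * ((j - 1) + frac) * w
  }

  lower <- outward_boundary(
    rev(conc[seq_len(m - 1)]),
    edge = centre[m] - w / 2, direction = -1
  )
  upper <- outward_boundary(
    conc[seq_len(nrow(dist)) > m],
    edge = centre[m] + w / 2, direction = 1
  )
  out <- tibble(mode = mode, lower = lower, upper = upper)
  structure(out, class = c("box_stats", class(out)))
}
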