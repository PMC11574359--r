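# Vesiculation dose-response assay.
#
# Vesiculation shows up in a sizing run as a reduction in mean liposome
# size and an increase in particle concentration. The concentration of
# particles in the bin centred at 82.5 nm serves as the marker of
# vesiculation efficiency across doses.

#' Dose-response summary of vesiculation distributions
#'
#' Extracts, for each dose, the marker-bin concentration, the mean
#' liposome size and the total particle concentration from the measured
#' size distributions. A dose-0 baseline is required.
#'
#' @param samples Named list mapping dose (uM, as names) to
#'   `size_distribution`, or a data frame with columns `dose` and a
#'   list-column `dist`.
#' @param metric_centre Marker bin centre in nm (default 82.5).
#' @return A tibble of class `vesiculation_result`, sorted by dose:
#'   `dose`, `metric` (particles/ml in the marker bin), `mean_size` (nm),
#'   `total_concentration` (particles/ml).
#' @export
vesiculation_dose_response <- function(samples, metric_centre = 82.5) {
  if (is.data.frame(samples)) {
    if (!all(c("dose", "dist") %in% names(samples))) {
      abort("`samples` needs columns `dose` and `dist`.")
    }
    doses <- as.numeric(samples$dose)
    dists <- samples$dist
  } else {
    if (!is.list(samples) || is.null(names(samples))) {
      abort("`samples` must be a named list (names = doses in uM).")
    }
    doses <- as.numeric(names(samples))
    dists <- unname(samples)
  }
  if (anyNA(doses)) abort("doses must be numeric.")
  if (length(doses) < 2L) abort("need at least 2 doses.")
  if (!any(doses == 0)) abort("a dose-0 baseline is required.")
  ord <- order(doses)
  out <- purrr::map_dfr(ord, function(i) {
    d <- dists[[i]]
    check_distribution(d)
    tibble(
      dose = doses[i],
      metric = bin_concentration_at(d, metric_centre),
      mean_size = mean_size(d),
      total_concentration = total_concentration(d)
    )
  })
  structure(out,
    metric_centre = metric_centre,
    class = c("vesiculation_result", class(out))
  )
}

#' Simulate a vesiculation dose series
#'
#' For each dose, draws the same baseline liposome population (same
#' substream seed, so dose effects are not confounded with sampling
#' noise), applies [vesiculate()], simulates Brownian tracks for every
#' particle, sizes and bins them, and summarises the series with
#' [vesiculation_dose_response()]. Vesiculation runs use fluorescent
#' liposomes, so all particles are labelled and tracked.
#'
#' @param spec A [population_spec()].
#' @param model A [vesiculation_model()]; its `dose` field is overridden
#'   by each element of `doses`.
#' @param doses Numeric vector of doses in uM, including 0.
#' @param medium,acq,seed,min_steps As in [curvature_assay()].
#' @param n_particles Baseline number of liposomes before vesiculation.
#' @param metric_centre Marker bin centre in nm.
#' @return A `vesiculation_result` tibble.
#' @export
vesiculation_assay <- function(spec, model, doses = c(0, 0.5, 1, 2, 4),
                               medium = medium_conditions(),
                               acq = acquisition_config(),
                               n_particles = 1000, seed = 1,
                               min_steps = 10, metric_centre = 82.5) {
  if (!inherits(model, "vesiculation_model")) {
    abort("`model` must be created with vesiculation_model().")
  }
  base <- sample_population(spec, n_particles, seed = derive_seed(seed, "population"))
  dists <- lapply(seq_along(doses), function(i) {
    sample_i <- simulated_sample(base, labelled = TRUE, volume = acq$observed_volume)
    ves <- vesiculate(
      sample_i, modifyList(model, list(dose = doses[i])),
      seed = derive_seed(seed, "vesiculate", i)
    )
    trk <- simulate_tracks(ves$diameter, medium, acq,
      seed = derive_seed(seed, "tracks", i), channel = "fluorescence"
    )
    est <- size_tracks(trk, medium,
      frame_interval = 1 / acq$frame_rate, min_steps = min_steps
    )
    bin_sizes(est, acq$observed_volume, channel = "fluorescence")
  })
  vesiculation_dose_response(
    setNames(dists, doses),
    metric_centre = metric_centre
  )
}

#' Compare vesiculation efficiency of two proteins at one dose
#'
#' Two-sided t-test on replicate marker-bin metrics at a shared dose
#' (e.g. wild-type versus a hyperactive mutant). Identical replicate sets
#' give a difference of 0 and p = 1.
#'
#' @param a,b Lists of `vesiculation_result` replicates (>= 3 each) on
#'   the same dose grid.
#' @param dose Dose (uM) at which to compare; must be on both grids.
#' @return A one-row tibble: `dose`, `difference` (mean metric of `a`
#'   minus mean metric of `b`), `statistic`, `p_value`.
#' @export
compare_efficiency <- function(a, b, dose) {
  metric_at <- function(res) {
    if (!inherits(res, "vesiculation_result")) {
      abort("replicates must be vesiculation_result objects.")
    }
    hit <- which(res$dose == dose)
    if (length(hit) != 1L) {
      abort(sprintf("dose %g uM is not on the result's dose grid.", dose))
    }
    res$metric[hit]
  }
  ma <- vapply(a, metric_at, numeric(1))
  mb <- vapply(b, metric_at, numeric(1))
  if (length(ma) < 3L || length(mb) < 3L) {
    abort("need at least 3 replicates per condition.")
  }
  diff_means <- mean(ma) - mean(mb)
  if (stats::sd(ma) == 0 && stats::sd(mb) == 0) {
    stat <- if (diff_means == 0) 0 else Inf
    p <- if (diff_means == 0) 1 else 0
  } else {
    tt <- stats::t.test(ma, mb, var.equal = TRUE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble(dose = dose, difference = diff_means, statistic = stat, p_value = p)
}
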