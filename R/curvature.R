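# Curvature-preference assay.
#
# The readout compares the size distribution of the total liposome
# population (diffraction channel) with that of the fluorescent,
# protein-bound subpopulation (fluorescence channel). A protein that
# prefers high curvature lights up the small end of the population, so
# the mode of the bound distribution sits below the total mode; a
# low-curvature binder shifts it above; an insensitive binder tracks the
# total. Replicate modes are the statistical unit.

#' Classify curvature preference from replicate modes
#'
#' Compares replicate mode values of the protein-bound subpopulation
#' against those of the total population. The mode shift is
#' `mean(bound) - mean(total)`; a preference is called only when the
#' shift exceeds `min_shift` in magnitude and the (Bonferroni-adjusted)
#' one-way ANOVA p-value is below `alpha`:
#' `smaller` for a significant negative shift (high-curvature
#' preference), `larger` for a significant positive shift, otherwise
#' `none`.
#'
#' @param total_modes Numeric vector of total-population replicate modes
#'   (nm), >= 3 replicates.
#' @param bound_modes Numeric vector of bound-subpopulation replicate
#'   modes (nm), same length as `total_modes`.
#' @param alpha Significance threshold (default 0.05).
#' @param min_shift Minimum mode shift in nm to call a preference;
#'   default 5 nm, one bin width (the resolution of the mode).
#' @param n_comparisons Bonferroni multiplier when this comparison is one
#'   of several (e.g. one per pore size); default 1.
#' @return A one-row tibble: `total_mode`, `bound_mode`, `shift_nm`,
#'   `p_adj`, `significance`, `class`.
#' @export
#' @examples
#' classify_preference(c(222.5, 217.5, 222.5), c(132.5, 137.5, 132.5))
classify_preference <- function(total_modes, bound_modes, alpha = 0.05,
                                min_shift = 5, n_comparisons = 1) {
  if (length(total_modes) != length(bound_modes)) {
    abort("replicate counts of `total_modes` and `bound_modes` differ.")
  }
  if (length(total_modes) < 3L) {
    abort("need at least 3 replicates per condition.")
  }
  check_prob(alpha, "alpha")
  res <- anova_oneway(list(total = total_modes, bound = bound_modes))
  p_adj <- min(1, n_comparisons * res$p_value)
  shift <- mean(bound_modes) - mean(total_modes)
  class <- if (p_adj < alpha && shift <= -min_shift) {
    "smaller"
  } else if (p_adj < alpha && shift >= min_shift) {
    "larger"
  } else {
    "none"
  }
  tibble(
    total_mode = mean(total_modes), bound_mode = mean(bound_modes),
    shift_nm = shift, p_adj = p_adj,
    significance = significance_tier(p_adj), class = class
  )
}

#' Curvature-preference classification across pore sizes
#'
#' Data-frame interface over [classify_preference()]: takes a tidy table
#' of replicate modes and classifies each pore size (or any other
#' condition), Bonferroni-correcting across conditions.
#'
#' @param data A data frame with columns `pore_size` (or any condition
#'   label), `replicate`, `total_mode`, `bound_mode`.
#' @param alpha,min_shift See [classify_preference()].
#' @return A tibble of class `curvature_result`, one row per condition.
#' @export
curvature_preference <- function(data, alpha = 0.05, min_shift = 5) {
  need <- c("pore_size", "total_mode", "bound_mode")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    abort("`data` needs columns pore_size, total_mode, bound_mode.")
  }
  conditions <- unique(data$pore_size)
  out <- purrr::map_dfr(conditions, function(ps) {
    rows <- data[data$pore_size == ps, ]
    dplyr::bind_cols(
      tibble(pore_size = ps, n_replicates = nrow(rows)),
      classify_preference(rows$total_mode, rows$bound_mode,
        alpha = alpha, min_shift = min_shift,
        n_comparisons = length(conditions)
      )
    )
  })
  structure(out,
    alpha = alpha, min_shift = min_shift,
    class = c("curvature_result", class(out))
  )
}

#' Simulate and classify a curvature-preference experiment
#'
#' End-to-end assay driver on the simulator: for each replicate, runs
#' [simulate_experiment()], sizes both channels with [size_tracks()],
#' bins them, and takes the raw-distribution mode per channel; the
#' replicate modes are then classified with [classify_preference()].
#'
#' @inheritParams simulate_experiment
#' @param n_replicates Number of experimental replicates (default 3).
#' @param min_steps Track-length filter passed to [size_tracks()].
#' @param alpha,min_shift Classification thresholds.
#' @return A `curvature_result` tibble (one row) with the replicate modes
#'   attached as attribute `replicates`.
#' @export
curvature_assay <- function(spec, binding, detection = detection_model(),
                            medium = medium_conditions(),
                            acq = acquisition_config(),
                            n_particles = 6000, n_replicates = 3, seed = 1,
                            min_steps = 10, alpha = 0.05, min_shift = 5) {
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    sim <- simulate_experiment(spec, binding, detection, medium, acq,
      n_particles = n_particles, seed = derive_seed(seed, "replicate", r)
    )
    est <- size_tracks(sim$tracks, medium,
      frame_interval = 1 / acq$frame_rate, min_steps = min_steps
    )
    modes <- vapply(c("diffraction", "fluorescence"), function(ch) {
      sub <- est[est$channel == ch, ]
      if (nrow(sub) == 0L) {
        return(NA_real_)
      }
      box_stats(bin_sizes(sub, acq$observed_volume, channel = ch))$mode
    }, numeric(1))
    tibble(
      replicate = r,
      total_mode = modes[["diffraction"]],
      bound_mode = modes[["fluorescence"]]
    )
  })
  if (anyNA(reps$total_mode) || anyNA(reps$bound_mode)) {
    abort("a replicate produced no sized tracks in one channel; increase n_particles.")
  }
  out <- classify_preference(reps$total_mode, reps$bound_mode,
    alpha = alpha, min_shift = min_shift
  )
  structure(
    dplyr::bind_cols(tibble(n_replicates = n_replicates), out),
    replicates = reps, alpha = alpha, min_shift = min_shift,
    class = c("curvature_result", class(out))
  )
}
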