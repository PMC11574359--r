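# broom-style accessors for the result types.

#' @export
tidy.curvature_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.curvature_result <- function(x, ...) {
  tibble(
    n_conditions = nrow(x),
    alpha = attr(x, "alpha"),
    min_shift = attr(x, "min_shift"),
    n_significant = sum(x$p_adj < attr(x, "alpha")),
    n_preference = sum(x$class != "none")
  )
}

#' @export
tidy.vesiculation_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.vesiculation_result <- function(x, ...) {
  base <- x$metric[x$dose == 0][1]
  top <- x$metric[which.max(x$dose)]
  tibble(
    n_doses = nrow(x),
    max_dose = max(x$dose),
    metric_centre = attr(x, "metric_centre"),
    baseline_metric = base,
    fold_change = if (base > 0) top / base else NA_real_,
    mean_size_drop = x$mean_size[x$dose == 0][1] - x$mean_size[which.max(x$dose)]
  )
}

#' @export
tidy.box_stats <- function(x, ...) {
  as_tibble(x)
}

#' @export
tidy.size_distribution <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.size_distribution <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    bin_width = attr(x, "bin_width"),
    channel = attr(x, "channel"),
    n_particles = attr(x, "n_particles"),
    total_concentration = total_concentration(x),
    mean_size = if (sum(x$concentration) > 0) mean_size(x) else NA_real_,
    mode = if (sum(x$concentration) > 0) box_stats(x)$mode else NA_real_
  )
}
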