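# ggplot2 methods for the result types.

#' @export
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$bin_centre, y = .data$concentration)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "diameter (nm)", y = "concentration (particles/ml)",
      title = attr(object, "label") %|na|% NULL,
      subtitle = if (!is.na(attr(object, "channel"))) {
        paste0(attr(object, "channel"), " channel")
      }
    ) +
    ggplot2::theme_minimal()
}

`%|na|%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

#' Overlay several size distributions
#'
#' Companion display to the assay scheme: the total population and the
#' protein-bound subpopulation on one axis, optionally smoothed the way
#' published curves are (7-point moving average).
#'
#' @param ... Named `size_distribution` objects (names become the legend).
#' @param smooth_window Odd moving-average window applied for display, or
#'   1 for raw curves.
#' @return A ggplot object.
#' @export
plot_distributions <- function(..., smooth_window = 1) {
  dists <- list(...)
  if (length(dists) == 1L && is.list(dists[[1]]) &&
    !inherits(dists[[1]], "size_distribution")) {
    dists <- dists[[1]]
  }
  if (is.null(names(dists)) || any(names(dists) == "")) {
    names(dists) <- paste0("distribution ", seq_along(dists))
  }
  df <- purrr::map_dfr(names(dists), function(nm) {
    d <- smooth_distribution(dists[[nm]], smooth_window)
    tibble(
      which = nm, bin_centre = d$bin_centre, concentration = d$concentration
    )
  })
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$bin_centre, y = .data$concentration, colour = .data$which
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "diameter (nm)", y = "concentration (particles/ml)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Mode-centred box plot of distributions
#'
#' Draws the assay's summary display: one box per distribution with the
#' mode as the middle line and the 50%-each-side boundaries as hinges.
#'
#' @param ... Named `size_distribution` objects.
#' @return A ggplot object.
#' @export
plot_box_stats <- function(...) {
  dists <- list(...)
  if (length(dists) == 1L && is.list(dists[[1]]) &&
    !inherits(dists[[1]], "size_distribution")) {
    dists <- dists[[1]]
  }
  if (is.null(names(dists)) || any(names(dists) == "")) {
    names(dists) <- paste0("distribution ", seq_along(dists))
  }
  df <- purrr::map_dfr(names(dists), function(nm) {
    dplyr::bind_cols(tibble(which = nm), box_stats(dists[[nm]]))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$which)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.3
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$mode, ymin = .data$lower, ymax = .data$upper),
      width = 0.5, fill = "grey90"
    ) +
    ggplot2::labs(x = NULL, y = "diameter (nm)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.vesiculation_result <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$dose, y = .data$metric)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "dose (uM)",
      y = sprintf(
        "concentration in %.1f-nm bin (particles/ml)",
        attr(object, "metric_centre")
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.curvature_result <- function(object, ...) {
  reps <- attr(object, "replicates")
  if (is.null(reps)) {
    abort("this curvature_result carries no replicate modes to plot.")
  }
  df <- tidyr::pivot_longer(reps,
    cols = c("total_mode", "bound_mode"),
    names_to = "population", values_to = "mode"
  ) |>
    dplyr::mutate(
      population = dplyr::recode(.data$population,
        total_mode = "total", bound_mode = "protein-bound"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$mode)) +
    ggplot2::geom_boxplot(width = 0.4, fill = "grey90") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "replicate mode (nm)",
      subtitle = sprintf(
        "class: %s (shift %.1f nm, p_adj %.3g)",
        object$class, object$shift_nm, object$p_adj
      )
    ) +
    ggplot2::theme_minimal()
}
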