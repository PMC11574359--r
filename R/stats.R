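# Replicate-level statistics.
#
# Because a single run sizes thousands of particles, per-particle tests
# would declare even trivial differences significant. The replicate unit
# is therefore the mode of each experimental run, and groups of replicate
# modes are compared by one-way ANOVA with Bonferroni-corrected pairwise
# post-hoc tests.

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("value", "group") %in% names(groups))) {
      abort("a data frame of replicate values needs columns `value` and `group`.")
    }
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L) {
    abort("need at least 2 groups of replicate values.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(lengths(groups) < 2L)) {
    abort("every group needs at least 2 replicate values.")
  }
  lapply(groups, as.numeric)
}

#' One-way ANOVA on replicate values
#'
#' Classical fixed-effects one-way ANOVA (between/within mean squares,
#' `k - 1` and `N - k` degrees of freedom), fitted with [stats::aov()].
#' Degenerate inputs where both mean squares are zero (all groups
#' identical and constant) are reported as `F = 0`, `p = 1`.
#'
#' @param groups Either a named list of numeric vectors (>= 2 values
#'   each), or a data frame with columns `value` and `group`.
#' @return A one-row tibble: `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, `ms_within`.
#' @export
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
anova_oneway <- function(groups) {
  g <- as_group_list(groups)
  df <- tibble(
    value = unlist(g, use.names = FALSE),
    group = factor(rep(names(g), lengths(g)))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (!is.finite(f)) { # 0/0 mean squares: identical constant groups
    f <- 0
    p <- 1
  }
  tibble(
    statistic = f, p_value = p,
    df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
    ms_within = tab[["Mean Sq"]][2]
  )
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Two-sided pooled-variance t-tests for selected group pairs, using the
#' ANOVA within-group mean square as the pooled variance (`N - k` degrees
#' of freedom, via [stats::pairwise.t.test()] with `pool.sd = TRUE`),
#' followed by the Bonferroni correction `p_adj = min(1, m * p)` with `m`
#' the number of requested comparisons.
#'
#' @inheritParams anova_oneway
#' @param comparisons List of length-2 character vectors naming group
#'   pairs to compare. Default: all pairs.
#' @return A tibble with one row per comparison: `group1`, `group2`,
#'   `difference` (mean of group2 minus mean of group1), `p_value`,
#'   `p_adj`.
#' @export
pairwise_bonferroni <- function(groups, comparisons = NULL) {
  g <- as_group_list(groups)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(names(g), 2, simplify = FALSE)
  }
  if (length(comparisons) == 0L) {
    abort("`comparisons` must name at least one pair.")
  }
  bad <- unique(unlist(comparisons))[!unique(unlist(comparisons)) %in% names(g)]
  if (length(bad)) {
    abort(paste0("unknown group(s): ", paste(bad, collapse = ", "), "."))
  }
  values <- unlist(g, use.names = FALSE)
  labels <- factor(rep(names(g), lengths(g)))
  raw <- suppressWarnings(stats::pairwise.t.test(
    values, labels,
    p.adjust.method = "none", pool.sd = TRUE
  ))$p.value
  lookup <- function(a, b) {
    if (a %in% rownames(raw) && b %in% colnames(raw) && !is.na(raw[a, b])) {
      raw[a, b]
    } else if (b %in% rownames(raw) && a %in% colnames(raw)) {
      raw[b, a]
    } else {
      NA_real_
    }
  }
  m <- length(comparisons)
  purrr::map_dfr(comparisons, function(pr) {
    p <- lookup(pr[2], pr[1])
    if (is.na(p)) p <- 1 # zero pooled variance and equal means
    tibble(
      group1 = pr[1], group2 = pr[2],
      difference = mean(g[[pr[2]]]) - mean(g[[pr[1]]]),
      p_value = p, p_adj = min(1, m * p)
    )
  })
}

#' Significance tier of a p-value
#'
#' The conventional star notation: `ns` for p >= 0.05, then `*` (< 0.05),
#' `**` (< 0.01), `***` (< 0.001), `****` (< 0.0001).
#'
#' @param p P-value(s).
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  cut(p,
    breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
    labels = c("****", "***", "**", "*", "ns")
  ) |> as.character()
}
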