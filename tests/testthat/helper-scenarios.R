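# Shared fixtures: canonical simulator scenarios and independent oracles.

# 800-nm-extruded polydisperse liposome preparation
pop_800 <- function() population_spec(220, 1.4, extrusion_cutoff = 800)

# preparation used for vesiculation runs (fluorescent liposomes)
pop_ves <- function() population_spec(140, 1.35, extrusion_cutoff = 400)

# reference binder scenarios: near-exclusive preferences
binder_high <- function(baseline = 0.02) {
  binding_model("high_curvature",
    midpoint = 150, steepness = 10,
    max_prob = 0.95, baseline_prob = baseline
  )
}
binder_none <- function() binding_model("insensitive", max_prob = 0.9)
binder_low <- function() {
  binding_model("low_curvature",
    midpoint = 250, steepness = 10,
    max_prob = 0.95, baseline_prob = 0.02
  )
}

# Brute-force textbook one-way ANOVA (independent of the package's wrapper):
# explicit between/within sums of squares.
brute_anova <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  k <- length(groups)
  N <- length(x)
  grand <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  f <- msb / msw
  list(
    f = f, p = pf(f, k - 1, N - k, lower.tail = FALSE),
    msw = msw, df2 = N - k
  )
}

# Brute-force pooled-variance pairwise t-test with Bonferroni cap.
brute_pairwise <- function(groups, pair, m) {
  o <- brute_anova(groups)
  a <- groups[[pair[1]]]
  b <- groups[[pair[2]]]
  t_stat <- (mean(b) - mean(a)) / sqrt(o$msw * (1 / length(a) + 1 / length(b)))
  p <- 2 * pt(-abs(t_stat), o$df2)
  list(p = p, p_adj = min(1, m * p))
}

# random replicate-group instance for the statistics oracle
random_groups <- function(k = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- k %||% sample(2:5, 1)
  g <- lapply(seq_len(k), function(i) rnorm(sample(2:8, 1), mean = runif(1, -2, 2)))
  names(g) <- letters[seq_len(k)]
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x
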