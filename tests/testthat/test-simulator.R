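test_that("population sampling respects the mixture and the extrusion cutoff", {
  spec <- population_spec(100, 1.3)
  d <- sample_population(spec, 1e5, seed = 1)
  expect_equal(median(d), 100, tolerance = 0.02)
  cut <- population_spec(100, 1.3, extrusion_cutoff = 200)
  d2 <- sample_population(cut, 2e4, seed = 2)
  expect_lte(max(d2), 200)
  # same seed -> identical draws
  expect_identical(
    sample_population(cut, 1000, seed = 7),
    sample_population(cut, 1000, seed = 7)
  )
  # two-component mixture puts mass at both medians
  mix <- population_spec(c(80, 300), c(1.2, 1.2), weight = c(0.5, 0.5))
  d3 <- sample_population(mix, 2e4, seed = 3)
  expect_gt(mean(d3 < 150), 0.4)
  expect_gt(mean(d3 > 150), 0.4)
})

test_that("population_spec validates its invariants", {
  expect_error(population_spec(100, 1), "> 1")
  expect_error(population_spec(-5, 1.3), "positive")
  expect_error(population_spec(100, 1.3, weight = -1), "non-negative")
  expect_error(population_spec(100, 1.3, extrusion_cutoff = 0), "positive")
})

test_that("binding probability covers the three curvature regimes", {
  ins <- binding_model("insensitive", max_prob = 0.7)
  expect_equal(binding_probability(c(20, 100, 900), ins), rep(0.7, 3))
  hc <- binding_model("high_curvature",
    midpoint = 150, steepness = 5,
    max_prob = 0.9, baseline_prob = 0.1
  )
  # logistic midpoint: halfway between baseline and max
  expect_equal(binding_probability(150, hc), 0.5)
  # asymptotes
  expect_equal(binding_probability(1e6, hc), 0.1, tolerance = 1e-4)
  expect_equal(binding_probability(1e-3, hc), 0.9, tolerance = 1e-4)
  # monotone decreasing in diameter
  p <- binding_probability(seq(20, 800, by = 20), hc)
  expect_true(all(diff(p) < 0))
  lc <- binding_model("low_curvature",
    midpoint = 250, steepness = 5,
    max_prob = 0.9, baseline_prob = 0.1
  )
  p2 <- binding_probability(seq(20, 800, by = 20), lc)
  expect_true(all(diff(p2) > 0))
})

test_that("labelling is Bernoulli at the model probability", {
  hc <- binder_high()
  # degenerate cases
  all_on <- binding_model("insensitive", max_prob = 1)
  expect_true(all(label_by_binding(runif(100, 50, 500), all_on, seed = 1)))
  none_on <- binding_model("insensitive", max_prob = 0, baseline_prob = 0)
  expect_false(any(label_by_binding(runif(100, 50, 500), none_on, seed = 1)))
  # binomial oracle at a fixed diameter: within 3 sd of expectation
  n <- 1e5
  d <- rep(120, n)
  p <- binding_probability(120, hc)
  frac <- mean(label_by_binding(d, hc, seed = 5))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("detection hides small particles in diffraction but not fluorescence", {
  det <- detection_model(diffraction_midpoint = 90, diffraction_steepness = 6)
  parts <- tibble::tibble(
    diameter = sample_population(population_spec(70, 1.3), 2e4, seed = 4),
    labelled = TRUE
  )
  seen_d <- apply_detection(parts, det, "diffraction", seed = 1)
  seen_f <- apply_detection(parts, det, "fluorescence", seed = 2)
  # hidden fraction: the diffraction-observed distribution is shifted high
  expect_gt(median(seen_d$diameter), median(parts$diameter) * 1.05)
  # fluorescence is size-blind
  expect_equal(median(seen_f$diameter), median(parts$diameter), tolerance = 0.03)
  # asymptote: large particles essentially always detected
  big <- tibble::tibble(diameter = rep(1000, 1000), labelled = FALSE)
  expect_gt(nrow(apply_detection(big, det, "diffraction", seed = 3)), 990)
  # fluorescence channel sees no unlabelled particles
  expect_equal(nrow(apply_detection(big, det, "fluorescence", seed = 3)), 0L)
  expect_error(apply_detection(parts, det, "scatter"), "channel")
})

test_that("simulated Brownian steps have the prescribed variance", {
  med <- medium_conditions()
  acq <- acquisition_config()
  trk <- simulate_track(100, med, acq, seed = 3, n_steps = 1e5)
  D <- diameter_to_diffusion(100, med)
  dt <- 1 / acq$frame_rate
  expect_equal(var(diff(trk$x_um)), 2 * D * dt, tolerance = 0.02)
  expect_equal(var(diff(trk$y_um)), 2 * D * dt, tolerance = 0.02)
  expect_equal(mean(diff(trk$x_um)), 0, tolerance = 0.01)
})

test_that("track bookkeeping: frames, lengths, determinism", {
  acq <- acquisition_config(frame_rate = 25, mean_track_length = 30)
  trk <- simulate_tracks(rep(100, 500), acq = acq, seed = 9)
  lens <- dplyr::count(trk, track_id)$n
  expect_true(all(lens >= 2))
  expect_lte(max(lens), 25 * 120)
  expect_equal(mean(lens), 30, tolerance = 0.15)
  # frames are 1..n per track
  per <- trk |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(ok = all(frame == seq_len(dplyr::n())))
  expect_true(all(per$ok))
  # per-track positions start at the origin
  first <- trk |>
    dplyr::group_by(track_id) |>
    dplyr::slice(1)
  expect_true(all(abs(first$x_um) < 1e-9 & abs(first$y_um) < 1e-9))
  expect_identical(
    simulate_tracks(rep(100, 50), acq = acq, seed = 5),
    simulate_tracks(rep(100, 50), acq = acq, seed = 5)
  )
})

test_that("experiment composition is seed-reproducible with consistent truth", {
  sim <- simulate_experiment(pop_800(), binder_none(),
    n_particles = 400, seed = 17
  )
  sim2 <- simulate_experiment(pop_800(), binder_none(),
    n_particles = 400, seed = 17
  )
  expect_identical(sim, sim2)
  expect_equal(nrow(sim$truth), 400L)
  # fluorescence tracks exist only for labelled particles
  expect_equal(
    sum(sim$truth$seen_fluorescence & !sim$truth$labelled), 0L
  )
  # track counts match observation flags
  n_diff <- dplyr::n_distinct(
    sim$tracks$track_id[sim$tracks$channel == "diffraction"]
  )
  expect_equal(n_diff, sum(sim$truth$seen_diffraction))
})

test_that("perfect detection with saturating insensitive binding sees every particle in both channels", {
  det <- detection_model(
    diffraction_midpoint = 1e-6, diffraction_steepness = 10,
    fluorescence_prob = 1
  )
  sim <- simulate_experiment(pop_800(), binding_model("insensitive", max_prob = 1),
    detection = det, n_particles = 300, seed = 23
  )
  counts <- dplyr::count(dplyr::distinct(sim$tracks, track_id, channel), channel)
  expect_equal(counts$n, c(300L, 300L))
})
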