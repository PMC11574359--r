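test_that("binning follows the half-open 5-nm edge convention", {
  d <- bin_sizes(c(82, 83, 101), observed_volume = 1e-6)
  expect_equal(bin_concentration_at(d, 82.5), 2e6)
  expect_equal(bin_concentration_at(d, 102.5), 1e6)
  expect_equal(attr(d, "n_particles"), 3L)
  # a diameter exactly on an edge falls in the upper bin
  d2 <- bin_sizes(85, observed_volume = 1e-6)
  expect_equal(d2$bin_centre, 87.5)
  # counts are conserved: sum(concentration) * volume = n
  expect_equal(sum(d$concentration) * 1e-6, 3)
  expect_equal(total_concentration(d) * 1e-6, 3)
})

test_that("bin grid carries interior zeros but trims the outside", {
  d <- bin_sizes(c(12, 43), observed_volume = 1e-6)
  expect_equal(d$bin_centre[1], 12.5)
  expect_equal(d$bin_centre[nrow(d)], 42.5)
  expect_true(any(d$concentration == 0))
  expect_equal(diff(d$bin_centre), rep(5, nrow(d) - 1))
})

test_that("empty input gives an empty distribution, not an error", {
  d <- bin_sizes(numeric(0), observed_volume = 1e-6)
  expect_equal(nrow(d), 0L)
  expect_equal(attr(d, "n_particles"), 0L)
})

test_that("moving-average smoothing matches its arithmetic", {
  # constant curve unchanged
  d <- bin_sizes(rep(seq(102, 142, by = 5), each = 3), observed_volume = 1e-6)
  expect_equal(smooth_distribution(d, 7)$concentration, d$concentration)
  # window 1 is the identity
  spike <- bin_sizes(rep(101, 7), observed_volume = 1e-6)
  expect_identical(smooth_distribution(spike, 1), spike)
  # an interior spike of height 7 spreads to 1 over seven bins
  # (padding bins sit far enough out not to share a window with the spike)
  diam <- c(rep(101, 7), 61, 151)
  sp <- bin_sizes(diam, observed_volume = 1e-6)
  sm <- smooth_distribution(sp, 7)
  inner <- which(sp$bin_centre %in% seq(87.5, 117.5, by = 5))
  expect_equal(sm$concentration[inner], rep(1e6, 7))
  expect_error(smooth_distribution(sp, 4), "odd")
})

test_that("correction factor matches its defining arithmetic", {
  fluo <- bin_sizes(rep(c(101, 106), c(4, 3)), observed_volume = 1e-6)
  diff <- bin_sizes(rep(c(101, 106), c(2, 3)), observed_volume = 1e-6)
  cf <- compute_cf(fluo, diff)
  expect_equal(cf$cf, c(1, 0)) # (4-2)/2 = 1, (3-3)/3 = 0
  expect_true(all(cf$valid))
  # identical curves give zero correction everywhere
  cf0 <- compute_cf(diff, diff)
  expect_equal(cf0$cf, c(0, 0))
  expect_equal(apply_cf(diff, cf0)$concentration, diff$concentration)
})

test_that("bins with no diffraction signal are flagged invalid and pass through", {
  al <- align_distributions(
    bin_sizes(c(52, 101), observed_volume = 1e-6),
    bin_sizes(101, observed_volume = 1e-6)
  )
  cf <- compute_cf(al$a, al$b)
  expect_false(cf$valid[1])
  expect_true(is.na(cf$cf[1]))
  expect_message(out <- apply_cf(al$b, cf), "uncorrected")
  expect_equal(out$concentration, al$b$concentration)
})

test_that("apply_cf(compute_cf()) reconstructs the fluorescence curve", {
  set.seed(42)
  for (i in 1:10) {
    d_f <- sample_population(population_spec(90, 1.4), 400)
    d_d <- sample_population(population_spec(120, 1.3), 300)
    al <- align_distributions(
      bin_sizes(d_f, observed_volume = 1e-6),
      bin_sizes(d_d, observed_volume = 1e-6)
    )
    cf <- compute_cf(al$a, al$b)
    rt <- apply_cf(al$b, cf)
    expect_equal(
      rt$concentration[cf$valid], al$a$concentration[cf$valid]
    )
  }
})

test_that("mismatched bin grids are rejected", {
  a <- bin_sizes(c(101, 106), observed_volume = 1e-6)
  b <- bin_sizes(c(101, 106, 111), observed_volume = 1e-6)
  expect_error(compute_cf(a, b), "grid")
  expect_error(apply_cf(b, compute_cf(a, a)), "grid")
})

test_that("the simulated hidden fraction is repaired by the CF", {
  # fully fluorescent calibration sample measured in both channels
  spec <- population_spec(85, 1.35, extrusion_cutoff = 200)
  det <- detection_model(diffraction_midpoint = 90, diffraction_steepness = 6)
  d <- sample_population(spec, 3e4, seed = 61)
  parts <- tibble::tibble(diameter = d, labelled = TRUE)
  obs_d <- apply_detection(parts, det, "diffraction", seed = 62)
  obs_f <- apply_detection(parts, det, "fluorescence", seed = 63)
  al <- align_distributions(
    bin_sizes(obs_f$diameter, observed_volume = 1e-5),
    bin_sizes(obs_d$diameter, observed_volume = 1e-5)
  )
  # the deficit is real before correction...
  expect_gt(
    box_stats(al$b)$mode, box_stats(al$a)$mode - 1e-9
  )
  expect_lt(total_concentration(al$b), total_concentration(al$a))
  # ...and a CF from a twin sample corrects an independent measurement
  d2 <- sample_population(spec, 3e4, seed = 71)
  parts2 <- tibble::tibble(diameter = d2, labelled = TRUE)
  al2 <- align_distributions(
    bin_sizes(apply_detection(parts2, det, "fluorescence", seed = 72)$diameter,
      observed_volume = 1e-5
    ),
    bin_sizes(apply_detection(parts2, det, "diffraction", seed = 73)$diameter,
      observed_volume = 1e-5
    )
  )
  cf <- regrid_cf(compute_cf(al2$a, al2$b), al$b)
  corrected <- suppressMessages(apply_cf(al$b, cf))
  fluo_ref <- al$a
  # corrected diffraction matches fluorescence within sampling error
  expect_equal(
    mean_size(corrected), mean_size(fluo_ref),
    tolerance = 0.05
  )
  expect_equal(
    total_concentration(corrected), total_concentration(fluo_ref),
    tolerance = 0.1
  )
})

test_that("summary accessors validate the grid and conserve mass", {
  d <- bin_sizes(rep(102, 5), observed_volume = 1e-6)
  expect_equal(mean_size(d), 102.5)
  expect_equal(bin_concentration_at(d, 202.5), 0) # off-range bin
  expect_error(bin_concentration_at(d, 84), "grid")
  w <- bin_sizes(c(82, 83, 101), observed_volume = 1e-6)
  expect_equal(bin_concentration_at(w, 82.5), 2e6)
})
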