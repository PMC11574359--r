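test_that("lag-1 MSD estimator matches its definition on tiny tracks", {
  # two-point track, displacement (2, 0) um, dt = 0.04 s -> 4 um^2 / 0.16 s
  expect_equal(lag1_diffusion(c(0, 2), c(0, 0), 0.04), 25)
  # stationary particle
  expect_equal(lag1_diffusion(rep(1, 10), rep(-3, 10), 0.04), 0)
  expect_error(lag1_diffusion(1, 1, 0.04), "2 positions")
  expect_error(lag1_diffusion(c(0, 1), c(0, 1), 0), "positive")
})

test_that("estimator recovers the true diffusion coefficient on a long track", {
  trk <- simulate_track(100, seed = 11, n_steps = 10000)
  D_true <- diameter_to_diffusion(100)
  D_hat <- lag1_diffusion(trk$x_um, trk$y_um, 1 / 25)
  expect_equal(D_hat, D_true, tolerance = 0.05)
})

test_that("estimate_diffusion works per track and channel", {
  trk <- dplyr::bind_rows(
    simulate_track(100, seed = 1, n_steps = 50, track_id = 1),
    simulate_track(200, seed = 2, n_steps = 80, track_id = 2, channel = "fluorescence")
  )
  est <- estimate_diffusion(trk)
  expect_equal(nrow(est), 2L)
  expect_equal(est$n_steps, c(50L, 80L))
  expect_equal(est$channel, c("diffraction", "fluorescence"))
  expect_true(all(est$diffusion_coeff > 0))
})

test_that("drift correction cancels a uniform flow exactly", {
  trk <- simulate_tracks(rep(150, 40), seed = 21, n_steps = 30)
  drifted <- trk |>
    dplyr::mutate(x_um = x_um + 0.8 * (frame - 1), y_um = y_um - 0.3 * (frame - 1))
  corr_plain <- drift_correct(trk)
  corr_drift <- drift_correct(drifted)
  # adding the same per-frame displacement to every track leaves the
  # corrected ensemble unchanged
  expect_equal(corr_drift$x_um, corr_plain$x_um, tolerance = 1e-10)
  expect_equal(corr_drift$y_um, corr_plain$y_um, tolerance = 1e-10)
  # ensemble-mean step is zero at every frame transition
  steps <- corr_drift |>
    dplyr::group_by(track_id) |>
    dplyr::mutate(dx = c(NA, diff(x_um))) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(dx)) |>
    dplyr::group_by(frame) |>
    dplyr::summarise(m = mean(dx))
  expect_true(all(abs(steps$m) < 1e-12))
})

test_that("drift-corrected diffusion estimates match the no-drift ensemble", {
  trk <- simulate_tracks(rep(100, 300), seed = 31, n_steps = 60)
  drifted <- trk |>
    dplyr::mutate(x_um = x_um + 0.8 * (frame - 1))
  D_plain <- mean(estimate_diffusion(trk)$diffusion_coeff)
  D_corr <- mean(estimate_diffusion(drift_correct(drifted))$diffusion_coeff)
  D_raw <- mean(estimate_diffusion(drifted)$diffusion_coeff)
  expect_gt(D_raw, D_plain * 1.5) # drift inflates the raw estimate
  expect_equal(D_corr, D_plain, tolerance = 0.05)
})

test_that("a single track passes through drift correction unchanged", {
  trk <- simulate_track(100, seed = 41, n_steps = 20)
  expect_warning(out <- drift_correct(trk), "one track")
  expect_equal(out$x_um, trk$x_um)
})

test_that("size_tracks filters, sizes and keeps channel tags", {
  trk <- dplyr::bind_rows(
    simulate_tracks(rep(100, 20), seed = 51, n_steps = 40),
    simulate_tracks(rep(100, 10),
      seed = 52, n_steps = 5,
      channel = "fluorescence", first_id = 21L
    )
  )
  est <- size_tracks(trk, min_steps = 10)
  expect_equal(nrow(est), 20L) # the 5-step tracks fall below the filter
  expect_setequal(unique(est$channel), "diffraction")
  expect_true(all(est$diameter > 0))
  # min_steps above every track length -> empty result, not an error
  expect_equal(nrow(size_tracks(trk, min_steps = 100)), 0L)
  # mixed channels preserved when both pass
  est_all <- size_tracks(trk, min_steps = 2)
  expect_setequal(unique(est_all$channel), c("diffraction", "fluorescence"))
  # estimates scatter around the simulated diameter
  expect_equal(median(est$diameter), 100, tolerance = 0.15)
})

test_that("stationary tracks are dropped with a message", {
  still <- tibble::tibble(
    track_id = 1L, frame = 1:20, x_um = 0, y_um = 0, channel = "diffraction"
  )
  expect_message(est <- size_tracks(still, min_steps = 5), "zero estimated diffusion")
  expect_equal(nrow(est), 0L)
})
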