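test_that("identical replicate modes are classified as no preference", {
  res <- classify_preference(c(200, 205, 210), c(200, 205, 210))
  expect_equal(res$class, "none")
  expect_equal(res$shift_nm, 0)
  expect_equal(res$p_adj, 1)
})

test_that("classification needs both a large shift and significance", {
  # large, consistent shift: significant and below -min_shift
  res <- classify_preference(c(220, 225, 220), c(130, 135, 130))
  expect_equal(res$class, "smaller")
  expect_lt(res$p_adj, 0.05)
  # significant but sub-threshold shift stays "none"
  res2 <- classify_preference(c(220, 220, 225), c(218, 218, 223),
    min_shift = 5
  )
  expect_equal(res2$class, "none")
  # large shift with hopeless replicate scatter stays "none"
  res3 <- classify_preference(c(150, 250, 350), c(120, 260, 310))
  expect_equal(res3$class, "none")
  # positive shift with significance
  res4 <- classify_preference(c(200, 205, 200), c(280, 285, 280))
  expect_equal(res4$class, "larger")
  expect_error(classify_preference(c(1, 2, 3), c(1, 2)), "replicate counts")
  expect_error(classify_preference(c(1, 2), c(1, 2)), "3 replicates")
})

test_that("curvature_preference classifies each pore size with Bonferroni correction", {
  df <- tibble::tibble(
    pore_size = rep(c(800, 200), each = 3),
    replicate = rep(1:3, 2),
    total_mode = c(220, 225, 220, 140, 145, 140),
    bound_mode = c(130, 135, 130, 141, 146, 141)
  )
  res <- curvature_preference(df)
  expect_s3_class(res, "curvature_result")
  expect_equal(res$class, c("smaller", "none"))
  # the adjusted p is doubled relative to a single-condition analysis
  single <- classify_preference(
    df$total_mode[1:3], df$bound_mode[1:3]
  )
  expect_equal(res$p_adj[1], min(1, 2 * single$p_adj))
  g <- glance(res)
  expect_equal(g$n_conditions, 2L)
  expect_equal(g$n_preference, 1L)
  expect_equal(nrow(tidy(res)), 2L)
})

test_that("dose-response summary extracts the marker bin per dose", {
  d0 <- bin_sizes(rep(c(82, 102), c(2, 8)), observed_volume = 1e-6)
  d1 <- bin_sizes(rep(c(82, 102), c(6, 4)), observed_volume = 1e-6)
  res <- vesiculation_dose_response(list("0" = d0, "2" = d1))
  expect_equal(res$dose, c(0, 2))
  expect_equal(res$metric, c(2e6, 6e6))
  expect_equal(res$metric[1], bin_concentration_at(d0, 82.5))
  # identical distributions give a flat metric
  flat <- vesiculation_dose_response(list("0" = d0, "1" = d0, "4" = d0))
  expect_equal(diff(flat$metric), c(0, 0))
  # doses come back sorted
  res2 <- vesiculation_dose_response(list("4" = d1, "0" = d0))
  expect_equal(res2$dose, c(0, 4))
  expect_error(vesiculation_dose_response(list("1" = d0, "2" = d1)), "dose-0")
  expect_error(vesiculation_dose_response(list("0" = d0)), "2 doses")
})

test_that("a stronger vesiculator scores higher at equal dose", {
  doses <- c(0, 1, 2)
  strong <- vesiculation_assay(pop_ves(), vesiculation_model(max_fraction = 0.8),
    doses = doses, n_particles = 600, seed = 5
  )
  weak <- vesiculation_assay(pop_ves(), vesiculation_model(max_fraction = 0.2),
    doses = doses, n_particles = 600, seed = 5
  )
  expect_gt(strong$metric[3], weak$metric[3])
  expect_lt(strong$mean_size[3], weak$mean_size[3])
  # vesiculation raises particle concentration and lowers mean size
  expect_gt(strong$total_concentration[3], strong$total_concentration[1])
  expect_lt(strong$mean_size[3], strong$mean_size[1])
})

test_that("compare_efficiency behaves on identical, ordered and swapped inputs", {
  mk <- function(metrics) {
    lapply(metrics, function(m) {
      structure(
        tibble::tibble(
          dose = c(0, 2), metric = c(1e6, m),
          mean_size = c(150, 100), total_concentration = c(1e8, 2e8)
        ),
        metric_centre = 82.5,
        class = c("vesiculation_result", class(tibble::tibble()))
      )
    })
  }
  a <- mk(c(5e6, 6e6, 7e6))
  b <- mk(c(2e6, 2.5e6, 3e6))
  res <- compare_efficiency(a, b, dose = 2)
  expect_gt(res$difference, 0)
  expect_lt(res$p_value, 0.05)
  swapped <- compare_efficiency(b, a, dose = 2)
  expect_equal(swapped$difference, -res$difference)
  expect_equal(swapped$p_value, res$p_value)
  same <- compare_efficiency(a, a, dose = 2)
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_efficiency(a, b, dose = 3), "dose grid")
})
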