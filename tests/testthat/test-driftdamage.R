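test_that("bin statistics follow the drift trajectory over indexed images", {
  truth <- generate_truth(tetragonal_cell(78.4, 38.4), d_min = 4, b_true = 10, seed = 2)
  n_img <- 1000
  dr <- drift_model(
    a = list(start = 78.44, end = 78.34, knot = 1), # linear over the whole run
    b = list(start = 78.44, end = 78.34, knot = 1),
    c = list(start = 38.38, end = 38.79, knot = 0.5)
  )
  st <- simulate_stream(truth, scan_geometry(10, 100),
    hits = hit_model(50, 1, 1), drift = dr,
    noise = noise_model(obs_fraction = 0.05), seed = 3
  )
  bins <- bin_cell_drift(st, n_bins = 10)
  expect_identical(nrow(bins), 10L)
  expect_equal(sum(bins$n_images), n_img)
  expect_equal(sum(bins$n_indexed), stream_summary(st)$n_indexed)
  expect_identical(bins$image_lo[1], 0L)
  expect_equal(bins$image_hi[10], n_img - 1)
  # all images indexed here, so bin means equal trajectory means (no jitter)
  traj_c <- function(i) {
    t <- i / (n_img - 1)
    ifelse(t <= 0.5, 38.38 + (38.79 - 38.38) * t / 0.5, 38.79)
  }
  expected_c <- sapply(split(0:(n_img - 1), rep(1:10, each = 100)), function(ix) {
    mean(traj_c(ix))
  })
  expect_equal(bins$c_mean, unname(expected_c), tolerance = 1e-9)
  # plateau: late bins constant at the end value, early bins near the start
  expect_equal(bins$c_mean[7:10], rep(38.79, 4))
  expect_lt(bins$c_mean[1], 38.45)
  expect_true(all(bins$a_sd[!bins$flagged] >= 0))
})

test_that("bins with no indexed images are flagged, not fatal", {
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 4, b_true = 10, seed = 2)
  st <- simulate_stream(truth, scan_geometry(1, 40),
    hits = hit_model(50, 1, 1), noise = noise_model(obs_fraction = 0.2), seed = 3
  )
  # mark the middle of the run as not indexed
  st$images$indexed[11:20] <- FALSE
  st$observations <- st$observations[!st$observations$image %in% 10:19, ]
  bins <- bin_cell_drift(st, n_bins = 4)
  expect_true(bins$flagged[2])
  expect_true(is.na(bins$c_mean[2]))
  expect_false(any(bins$flagged[-2]))
})

test_that("percent change matches the reference cell arithmetic", {
  expect_equal(round(percent_change(38.38, 38.79), 0), 1)
  expect_equal(percent_change(38.38, 38.79), 100 * 0.41 / 38.38, tolerance = 1e-12)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(round(percent_change(78.44, 78.34), 3), -0.127)
  expect_error(percent_change(0, 1), class = "ssrox_error_drift")
})

test_that("the Wilson fit recovers the generative B factor", {
  cell <- tetragonal_cell(78.4, 38.4)
  # noiseless exponential decay: exact recovery
  refl <- enumerate_unique_hkl(cell, 1.8, "4/mmm")
  exact <- tibble::tibble(s = refl$s, i_merged = 200 * exp(-30 * refl$s / 2))
  fit <- wilson_b(exact, s_min = 0.05)
  # shell averaging of the exponential leaves a small Jensen bias
  expect_equal(fit$b_wilson, 30, tolerance = 0.01)
  # flat intensities: B = 0
  flat <- tibble::tibble(s = refl$s, i_merged = rep(7, nrow(refl)))
  expect_equal(wilson_b(flat, s_min = 0.05)$b_wilson, 0, tolerance = 1e-9)
  # sampled Wilson intensities: recovery within 5%
  truth <- generate_truth(cell, d_min = 1.8, b_true = 30, sigma0 = 50, seed = 5)
  fit2 <- wilson_b(truth$reflections, s_min = 0.05)
  expect_lt(abs(fit2$b_wilson - 30) / 30, 0.05)
})

test_that("damage shifts the fitted Wilson B by beta times dose applied", {
  cell <- tetragonal_cell(78.4, 38.4)
  truth <- generate_truth(cell, d_min = 1.8, b_true = 13, sigma0 = 100, seed = 8)
  dm <- damage_model(beta = 15, dose_fraction_applied = 0.5)
  dose <- 0.83 # MGy
  damaged <- tibble::tibble(
    s = truth$reflections$s,
    i_merged = apply_damage(truth$reflections$i_true, truth$reflections$s, dose, dm)
  )
  fit <- wilson_b(damaged, s_min = 0.05)
  expected <- 13 + 15 * 0.5 * dose # B_true + beta * f * D
  expect_lt(abs(fit$b_wilson - expected) / expected, 0.1)
})

test_that("B ratio series behaves like the damage metric", {
  expect_equal(b_ratio_series(10, c(10, 10))$ratio, c(1, 1))
  # reference and high-dose overall B of the damage series
  expect_equal(round(b_ratio_series(13.16, 23.18)$ratio, 3), 0.568)
  r <- b_ratio_series(13.16, c(13.13, 13.60, 15.46, 19.02, 23.18))
  expect_true(all(diff(r$ratio) < 0)) # strictly decreasing in B_n
  expect_error(b_ratio_series(10, c(5, -1)), class = "ssrox_error_wilson")
})
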