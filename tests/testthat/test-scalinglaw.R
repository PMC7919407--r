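ref_model <- function() log_scaling_model(a_slope = 0.044, b_scale = 6.5e-11)

test_that("noiseless points are recovered exactly and degenerate input errors", {
  N <- exp(seq(log(2e12), log(1.3e14), length.out = 10))
  pts <- tibble::tibble(n_photon = N, inv_d2 = 0.044 * log(6.5e-11 * N))
  m <- fit_log_model(pts)
  expect_equal(m$a_slope, 0.044, tolerance = 1e-9)
  expect_equal(m$b_scale, 6.5e-11, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  # two points: exact interpolation, zero residuals
  m2 <- fit_log_model(pts[c(1, 10), ])
  expect_equal(m2$residuals, c(0, 0), tolerance = 1e-12)
  # a `d` column works too
  ptsd <- tibble::tibble(n_photon = N, d = 1 / sqrt(pts$inv_d2))
  expect_equal(fit_log_model(ptsd)$a_slope, 0.044, tolerance = 1e-9)
  expect_error(
    fit_log_model(tibble::tibble(n_photon = rep(1e13, 3), inv_d2 = 1:3)),
    class = "ssrox_error_scaling"
  )
})

test_that("resolution predictions reproduce the planning anchors", {
  m <- ref_model()
  # 2000 images at 9.3e9 photons each reach 1.8 A at one decimal
  d <- predict_resolution(m, total_photons(2000, 9.3e9))
  expect_equal(round(d, 1), 1.8)
  expect_equal(d, (0.044 * log(6.5e-11 * 2000 * 9.3e9))^-0.5, tolerance = 1e-12)
  # unit inversion: a ln(bN) = 1 gives d = 1 exactly
  n_unit <- exp(1 / 0.044) / 6.5e-11
  expect_equal(predict_resolution(m, n_unit), 1, tolerance = 1e-12)
  expect_error(predict_resolution(m, 1 / 6.5e-11), class = "ssrox_error_scaling")
  # continuity above the threshold: d grows without bound as N falls to N0
  expect_gt(predict_resolution(m, zero_crossing(m) * 1.0001), 20)
})

test_that("the zero crossing is the reciprocal of b", {
  expect_equal(zero_crossing(ref_model()), 1 / 6.5e-11, tolerance = 1e-12)
  expect_equal(signif(zero_crossing(ref_model()), 2), 1.5e10)
  expect_equal(zero_crossing(log_scaling_model(1, 1)), 1)
})

test_that("images_needed inverts the law with correct ceiling behaviour", {
  m <- ref_model()
  n <- images_needed(m, d_target = 1.8, photons_image = 9.3e9)
  expect_equal(n, 1841L)
  # bracketing: n images suffice, n - 1 do not
  expect_lte(predict_resolution(m, n * 9.3e9), 1.8)
  expect_gt(predict_resolution(m, (n - 1) * 9.3e9), 1.8)
  # doubling the photons per image halves the count up to ceiling effects
  n2 <- images_needed(m, 1.8, 2 * 9.3e9)
  expect_lte(abs(n2 - ceiling(n / 2)), 1)
  # round trip over a range of targets
  for (d in c(3, 2.2, 1.7)) {
    ni <- images_needed(m, d, 9.3e9)
    expect_lte(predict_resolution(m, ni * 9.3e9), d)
  }
})

test_that("the Wilson interpretation is algebraically self-consistent", {
  m <- ref_model()
  # constants chosen self-consistently reproduce b exactly
  n_atoms <- 8000
  c_const <- 1e-9
  i_min <- 21.3 * n_atoms * c_const / 6.5e-11
  wi <- wilson_interpretation(m, n_atoms = n_atoms, c_const = c_const, i_min = i_min)
  expect_equal(wi$k, m$b_scale, tolerance = 1e-12)
  expect_equal(wi$n0, 1 / 6.5e-11, tolerance = 1e-12)
  # partial report: missing constants flag K as unavailable
  wi2 <- wilson_interpretation(m, n_atoms = n_atoms)
  expect_true(is.na(wi2$k))
  expect_false(is.na(wi2$n0))
  # no mapping registered: B flagged unavailable
  wi3 <- wilson_interpretation(m, b_mapping = NULL)
  expect_true(is.na(wi3$b_wilson_from_a))
})

test_that("the default slope-to-B mapping reproduces the reference overall B", {
  # a = 0.044 maps to 35.3 A^2 under the exponential scattering-factor model
  expect_equal(round(b_from_slope(0.044), 1), 35.3)
  wi <- wilson_interpretation(ref_model())
  expect_equal(round(wi$b_wilson_from_a, 1), 35.3)
})

test_that("fit then predict closes on the fitted points within residuals", {
  N <- exp(seq(log(2e12), log(1.3e14), length.out = 12))
  set.seed(3)
  pts <- tibble::tibble(
    n_photon = N,
    inv_d2 = 0.044 * log(6.5e-11 * N) + rnorm(12, 0, 0.003)
  )
  m <- fit_log_model(pts)
  pred_inv_d2 <- 1 / predict_resolution(m, pts$n_photon)^2
  expect_equal(pred_inv_d2, pts$inv_d2 - m$residuals, tolerance = 1e-9)
  gl <- glance(m)
  expect_gt(gl$r_squared, 0.99)
  expect_s3_class(autoplot(m), "ggplot")
})
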