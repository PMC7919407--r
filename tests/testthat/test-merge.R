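test_that("the Lorentz factor matches hand trigonometry and round-trips", {
  # wavelength 1 A, d = 2 A: sin(theta) = 0.25, L = 1/sin(2*theta)
  expect_equal(lorentz_factor(0.25, 1), 1 / sin(2 * asin(0.25)), tolerance = 1e-12)
  expect_equal(round(lorentz_factor(0.25, 1), 4), 2.0656)
  # round trip: multiply then divide recovers the input
  s <- c(0.04, 0.2, 0.4)
  i0 <- c(10, 5, 1)
  expect_equal(i0 * lorentz_factor(s, 1) / lorentz_factor(s, 1), i0, tolerance = 1e-12)
  # strictly decreasing in s while 2*theta < 90 deg (d >= 1.4 A at 1 A)
  sgrid <- seq(0.01, 1 / 1.4^2, length.out = 100)
  expect_true(all(diff(lorentz_factor(sgrid, 1)) < 0))
  expect_error(lorentz_factor(4.1, 1), class = "ssrox_error_lorentz")
})

test_that("image scaling recovers relative scales on an exact stream", {
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 2.5, b_true = 5, seed = 4)
  # identical images: all scales 1 after normalisation
  st_flat <- make_exact_stream(truth, rep(1, 6))
  sc <- estimate_image_scales(st_flat, n_iterations = 2)
  expect_equal(sc$scale, rep(1, 6), tolerance = 1e-12)
  # one image doubled: its scale sits at exactly twice the others
  st_double <- make_exact_stream(truth, c(1, 1, 2, 1, 1))
  sc2 <- estimate_image_scales(st_double, n_iterations = 2)
  expect_equal(sc2$scale[3] / sc2$scale[1], 2, tolerance = 1e-6)
  expect_equal(exp(mean(log(sc2$scale))), 1, tolerance = 1e-12) # geometric mean 1
  # with many unit images the doubled one approaches 2 on the absolute scale
  st_many <- make_exact_stream(truth, c(rep(1, 39), 2))
  sc3 <- estimate_image_scales(st_many, n_iterations = 3)
  expect_equal(sc3$scale[40], 2, tolerance = 0.05)
})

test_that("estimated scales track the simulator's hidden log-normal scales", {
  truth <- generate_truth(tetragonal_cell(78.4, 38.4), d_min = 1.7, b_true = 13, seed = 6)
  # counting noise suppressed: huge gain, no background, no read noise
  st <- simulate_stream(
    truth, scan_geometry(1, 60),
    hits = hit_model(50, 1, 1),
    noise = noise_model(
      obs_fraction = 0.7, scale_sdlog = 1.0,
      gain = 1e-6, background_per_photon = 0, read_noise_sd = 0
    ),
    seed = 13
  )
  sc <- estimate_image_scales(st)
  truth_scales <- st$images$scale_true[match(sc$image, st$images$image)]
  expect_gte(cor(sc$scale, truth_scales), 0.999)
})

test_that("merging reproduces scaled truth exactly on a noiseless stream", {
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 2.5, b_true = 5, seed = 4)
  g <- c(0.5, 1, 2, 4)
  st <- make_exact_stream(truth, g)
  merged <- monte_carlo_merge(st, scales = tibble::tibble(image = 0:3, scale = g))
  key <- paste(merged$h, merged$k, merged$l)
  tkey <- paste(truth$reflections$h, truth$reflections$k, truth$reflections$l)
  i_true <- truth$reflections$i_true[match(key, tkey)]
  expect_equal(merged$i_merged, i_true, tolerance = 1e-9)
  expect_true(all(merged$m == 4))
  expect_true(all(merged$n_even == 2 & merged$n_odd == 2))
})

test_that("half sets split by image parity and single observations are flagged", {
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 4, b_true = 5, seed = 4)
  st <- make_exact_stream(truth, rep(1, 10))
  merged <- monte_carlo_merge(st)
  expect_true(all(merged$n_even == 5 & merged$n_odd == 5))
  # single image: sigma and the odd half are undefined
  st1 <- make_exact_stream(truth, 1)
  m1 <- monte_carlo_merge(st1)
  expect_true(all(m1$m == 1))
  expect_true(all(is.na(m1$sigma_merged)))
  expect_true(all(is.na(m1$i_odd)))
  expect_true(all(m1$n_odd == 0))
  # missing scales for observed images are rejected
  expect_error(
    monte_carlo_merge(st, scales = tibble::tibble(image = 0L, scale = 1)),
    class = "ssrox_error_merge"
  )
})

test_that("rsplit matches hand arithmetic and is scale invariant", {
  toy <- tibble::tibble(
    i_even = c(10, 20), i_odd = c(12, 18),
    n_even = c(1, 1), n_odd = c(1, 1)
  )
  expect_equal(rsplit(toy), 100 / sqrt(2) * 4 / 30, tolerance = 1e-12)
  expect_equal(round(rsplit(toy), 3), 9.428)
  same <- tibble::tibble(i_even = c(3, 7), i_odd = c(3, 7), n_even = 1:2, n_odd = 1:2)
  expect_equal(rsplit(same), 0)
  scaled <- toy
  scaled$i_even <- toy$i_even * 37.5
  scaled$i_odd <- toy$i_odd * 37.5
  expect_equal(rsplit(scaled), rsplit(toy), tolerance = 1e-12)
  none <- tibble::tibble(i_even = 1, i_odd = NA_real_, n_even = 1, n_odd = 0)
  expect_error(rsplit(none), class = "ssrox_error_merge")
})

test_that("cc_half matches its closed-form expectation under added noise", {
  h <- tibble::tibble(
    i_even = c(1, 2, 3), i_odd = c(1, 2, 3),
    n_even = 1, n_odd = 1
  )
  expect_equal(cc_half(h), 1)
  h$i_odd <- -h$i_odd
  expect_equal(cc_half(h), -1)
  expect_true(is.na(cc_half(h[1:2, ]))) # fewer than 3 pairs
  flat <- tibble::tibble(i_even = rep(1, 5), i_odd = 1:5, n_even = 1, n_odd = 1)
  expect_true(is.na(cc_half(flat))) # zero variance
  # CC ~ var(signal) / (var(signal) + var(noise))
  set.seed(42)
  n <- 2000
  sig <- rnorm(n, 0, 2)
  tb <- tibble::tibble(
    i_even = sig + rnorm(n), i_odd = sig + rnorm(n),
    n_even = 1, n_odd = 1
  )
  expected <- 4 / (4 + 1)
  se <- (1 - expected^2) / sqrt(n - 3) # Fisher-z scale approximation
  expect_lt(abs(cc_half(tb) - expected), 3 * se)
})

test_that("merged error shrinks as one over the square root of the image count", {
  truth <- small_truth()
  rmse_at <- function(n_img) {
    st <- head_indexed(small_stream(), n_img)
    merged <- monte_carlo_merge(st)
    key <- paste(merged$h, merged$k, merged$l)
    tkey <- paste(truth$reflections$h, truth$reflections$k, truth$reflections$l)
    i_true <- truth$reflections$i_true[match(key, tkey)]
    # partiality is uniform (0,1], so the merged mean estimates i_true / 2
    sqrt(mean((merged$i_merged - i_true / 2)^2))
  }
  ratio <- rmse_at(200) / rmse_at(800)
  expect_lt(abs(ratio - 2) / 2, 0.2)
})

test_that("half-set noise realisations are uncorrelated", {
  truth <- small_truth()
  merged <- monte_carlo_merge(head_indexed(small_stream(), 900))
  key <- paste(merged$h, merged$k, merged$l)
  tkey <- paste(truth$reflections$h, truth$reflections$k, truth$reflections$l)
  i_true <- truth$reflections$i_true[match(key, tkey)]
  ok <- is.finite(merged$i_even) & is.finite(merged$i_odd)
  # regress out the shared signal so only the half-set noise remains
  res_even <- residuals(lm(merged$i_even[ok] ~ i_true[ok]))
  res_odd <- residuals(lm(merged$i_odd[ok] ~ i_true[ok]))
  r <- cor(res_even, res_odd)
  expect_lt(abs(r), 3 / sqrt(sum(ok) - 3))
})
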