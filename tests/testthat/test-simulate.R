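test_that("the standard helical geometry yields 22200 images per data set", {
  geom <- scan_geometry(n_scans = 100, images_per_scan = 222)
  expect_identical(geom$total_images, 22200L)
  # a full acquisition with no crystals still emits every image record
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 4, b_true = 10, seed = 1)
  st <- simulate_stream(truth, geom, hits = hit_model(lambda_crystals = 0), seed = 1)
  expect_identical(nrow(st$images), 22200L)
  expect_identical(stream_summary(st)$n_hits, 0L)
  expect_identical(stream_summary(st)$n_indexed, 0L)
  expect_identical(nrow(st$observations), 0L)
  # acquisition order is scan-major with 0-based indices
  expect_identical(st$images$image, 0:22199)
  expect_identical(st$images$scan[223], 1L)
})

test_that("hit and index rates match the Poisson/geometric law at 3 sigma", {
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 4, b_true = 10, seed = 1)
  hm <- hit_model(lambda_crystals = 1, q1 = 0.8, gamma_multi = 0.5)
  st <- simulate_stream(
    truth, scan_geometry(100, 222),
    hits = hm, noise = noise_model(obs_fraction = 0.02), seed = 5
  )
  cs <- stream_summary(st)
  n <- cs$n_images
  # hit probability oracle: 1 - exp(-lambda)
  p_hit <- 1 - exp(-1)
  se_hit <- sqrt(p_hit * (1 - p_hit) / n)
  expect_lt(abs(cs$n_hits / n - p_hit), 3 * se_hit)
  # index-of-hits oracle: sum_{k>=1} P(k) q1 gamma^(k-1) / P(k>=1)
  k <- 1:60
  p_index <- sum(dpois(k, 1) * 0.8 * 0.5^(k - 1)) / p_hit
  se_idx <- sqrt(p_index * (1 - p_index) / cs$n_hits)
  expect_lt(abs(cs$n_indexed / cs$n_hits - p_index), 3 * se_idx)
  # per-image flag invariants
  expect_true(all(st$images$hit == (st$images$n_lattices >= 1)))
  expect_true(all(!st$images$indexed | st$images$hit))
  expect_setequal(unique(st$observations$image), st$images$image[st$images$indexed])
})

test_that("denser loading raises the hit rate but lowers the index rate of hits", {
  lambdas <- c(0.25, 0.5, 1, 2, 4)
  hr <- sapply(lambdas, function(l) ssrox:::hit_rate_expected(hit_model(l, 0.8, 0.5)))
  ir <- sapply(lambdas, function(l) ssrox:::index_rate_expected(hit_model(l, 0.8, 0.5)))
  expect_true(all(diff(hr) > 0))
  expect_true(all(diff(ir) < 0))
  # empirical check at the extremes, 3 sigma
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 4, b_true = 10, seed = 1)
  rates <- lapply(c(0.25, 4), function(l) {
    st <- simulate_stream(
      truth, scan_geometry(50, 222),
      hits = hit_model(l, 0.8, 0.5),
      noise = noise_model(obs_fraction = 0.02), seed = 17
    )
    stream_summary(st)
  })
  n <- rates[[1]]$n_images
  hit_lo <- rates[[1]]$n_hits / n
  hit_hi <- rates[[2]]$n_hits / n
  # analytic gap is 0.98 - 0.22; require well over 3 sigma of it empirically
  expect_gt(hit_hi - hit_lo, 0.5)
  idx_lo <- rates[[1]]$n_indexed / rates[[1]]$n_hits
  idx_hi <- rates[[2]]$n_indexed / rates[[2]]$n_hits
  # analytic gap is 0.74 - 0.13
  expect_gt(idx_lo - idx_hi, 0.3)
})

test_that("identical seeds and configs give bit-identical streams", {
  truth <- generate_truth(tetragonal_cell(30, 20), d_min = 3.2, b_true = 10, seed = 2)
  geom <- scan_geometry(2, 60)
  st1 <- simulate_stream(truth, geom, seed = 9)
  st2 <- simulate_stream(truth, geom, seed = 9)
  expect_identical(st1$images, st2$images)
  expect_identical(st1$observations, st2$observations)
  st3 <- simulate_stream(truth, geom, seed = 10)
  expect_false(identical(st1$observations, st3$observations))
})

test_that("stream summaries count flags exactly, including empty streams", {
  st <- small_stream()
  cs <- stream_summary(st)
  expect_identical(cs$n_images, nrow(st$images))
  expect_identical(cs$n_hits, sum(st$images$hit))
  expect_identical(cs$n_indexed, sum(st$images$indexed))
  empty <- st
  empty$images <- st$images[0, ]
  empty$observations <- st$observations[0, ]
  expect_equal(unlist(stream_summary(empty)), c(n_images = 0, n_hits = 0, n_indexed = 0))
})
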