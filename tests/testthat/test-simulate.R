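test_that("the phantom realizes the stated geometry/orientation structure", {
  ph <- make_phantom()
  expect_equal(ph$field$dims, c(15L, 15L))
  expect_equal(sum(ph$truth), 81)
  expect_equal(sum(ph$labels == 1), 6)   # one foreground stroke
  expect_equal(sum(ph$labels == 2), 18)  # two background strokes
  expect_true(all(ph$labels[ph$truth == 1] != 2))

  ## across the internal orientation-band boundary: geometry distance 0,
  ## orientation distance 1; across the ROI border geometry separates
  fe <- compute_features(ph$field)
  row <- 8
  i_band1 <- (6 - 1) * 15 + row   # column 6, band 1 (0 deg)
  i_band2 <- (7 - 1) * 15 + row   # column 7, band 2 (90 deg)
  d_int <- original_distance(fe, i_band1, i_band2)
  expect_equal(unname(d_int), c(0, 0, 0, 1), tolerance = 1e-10)
  i_bg <- (2 - 1) * 15 + row      # background column
  d_roi_bg <- original_distance(fe, i_band1, i_bg)
  expect_true(all(d_roi_bg[1:3] == 1))

  ## determinism: regeneration is bit-identical
  ph2 <- make_phantom()
  expect_identical(ph2$field$tensors, ph$field$tensors)
  expect_identical(ph2$labels, ph$labels)

  expect_error(make_phantom(phantom_spec(roi_rows = integer())), "empty")
})

test_that("a single-orientation, geometry-distinct phantom is separable by all methods", {
  spec <- phantom_spec(roi_orientations = 0, bg_orientations = 0)
  ph <- make_phantom(spec)
  for (m in c("euclidean", "jdivergence", "geodesic", "learned")) {
    res <- segment_field(ph$field, ph$labels, method = m)
    expect_equal(dice(res$seg, ph$truth), 1)
  }
})

test_that("Stejskal-Tanner signals follow the attenuation law", {
  ph <- make_phantom()
  ## b = 0: baseline everywhere
  dwi0 <- stejskal_tanner(ph$field, bval = 0, S0 = 50)
  expect_equal(dwi0$signals[ph$field$valid, ],
               matrix(50, sum(ph$field$valid), 12), ignore_attr = TRUE)

  ## hand-computed exponent: D = diag(1.7e-3, 1e-4, 1e-4), g = x, b = 1000
  fld <- tensor_field(matrix(c(1.7e-3, 0, 0, 1e-4, 0, 1e-4), 1),
                      dims = c(1, 1))
  dwi <- stejskal_tanner(fld, bvecs = rbind(c(1, 0, 0), c(0, 1, 0),
                                            c(0, 0, 1), diag(3)[, 1],
                                            c(0, 1, 0), c(0, 0, 1)),
                         bval = 1000, S0 = 100)
  expect_equal(dwi$signals[1, 1], 100 * exp(-1.7), tolerance = 1e-12)

  ## attenuation is monotone in b
  s_b <- vapply(c(0, 500, 1000, 2000), function(b) {
    stejskal_tanner(fld, bval = b, S0 = 100)$signals[1, 1]
  }, numeric(1))
  expect_true(all(diff(s_b) < 0))

  expect_error(stejskal_tanner(fld, bvecs = rbind(c(2, 0, 0))), "unit norm")
})

test_that("Rician noise matches the Rayleigh closed form at zero signal", {
  ## S = 0: the magnitude is Rayleigh(sigma) with mean sigma * sqrt(pi/2)
  n_draw <- 1e5
  fld <- tensor_field(
    matrix(rep(1e-3 * c(1, 0, 0, 1, 0, 1), n_draw / 4), ncol = 6, byrow = TRUE),
    dims = c(n_draw / 4 / 25, 25))
  dwi <- stejskal_tanner(fld, bvecs = default_bvecs()[1:4, ], S0 = 100)
  dwi$signals[] <- 0
  snr <- 10
  sigma <- 100 / snr
  noisy <- add_rician_noise(dwi, snr = snr, seed = 99)
  draws <- as.numeric(noisy$signals)
  mean_rayleigh <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt((4 - pi) / 2) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean_rayleigh), 3 * se)

  ## sigma -> 0 limit: the signal is untouched
  dwi$signals[] <- 70
  almost_clean <- add_rician_noise(dwi, snr = 1e9, seed = 1)
  expect_equal(almost_clean$signals, dwi$signals, tolerance = 1e-5)
  expect_error(add_rician_noise(dwi, snr = 0), "snr")
})

test_that("the empirical SNR of a noisy constant image matches the convention", {
  ## sigma = S0 / snr on each complex channel: at high SNR the magnitude sd
  ## approaches sigma, so S0 / sd(noisy) recovers the nominal snr
  n_draw <- 1e4
  fld <- tensor_field(
    matrix(rep(1e-3 * c(1, 0, 0, 1, 0, 1), n_draw), ncol = 6, byrow = TRUE),
    dims = c(n_draw / 100, 100))
  dwi <- stejskal_tanner(fld, bvecs = rbind(c(1, 0, 0)), bval = 0, S0 = 100)
  noisy <- add_rician_noise(dwi, snr = 20, seed = 7)
  snr_hat <- 100 / stats::sd(noisy$signals[, 1])
  expect_lt(abs(snr_hat - 20) / 20, 0.1)
})

test_that("noise-free LLS fitting inverts the signal synthesis exactly", {
  set.seed(55)
  fld <- random_field(c(5, 4))
  dwi <- stejskal_tanner(fld)
  back <- fit_tensors_lls(dwi)
  expect_equal(back$tensors, fld$tensors, tolerance = 1e-8)

  ## phantom pipeline identity
  ph <- make_phantom()
  back2 <- fit_tensors_lls(stejskal_tanner(ph$field))
  expect_equal(back2$tensors, ph$field$tensors, tolerance = 1e-8)
  expect_identical(noisy_field(ph$field, snr = Inf), ph$field)

  ## isotropic field: no spurious anisotropy without noise
  iso <- tensor_field(matrix(rep(1e-3 * c(1, 0, 0, 1, 0, 1), 9), 9, 6,
                             byrow = TRUE), dims = c(3, 3))
  fa <- compute_features(fit_tensors_lls(stejskal_tanner(iso)))$fa
  expect_lt(max(fa), 1e-8)
})

test_that("tensor estimation demands an identifiable design", {
  ph <- make_phantom()
  dwi <- stejskal_tanner(ph$field, bvecs = default_bvecs()[1:5, ])
  expect_error(fit_tensors_lls(dwi), "at least 6")
  ## 6 directions but rank-deficient (all in one plane)
  th <- seq(0, pi, length.out = 7)[1:6]
  planar <- cbind(cos(th), sin(th), 0)
  dwi2 <- stejskal_tanner(ph$field, bvecs = planar)
  expect_error(fit_tensors_lls(dwi2), "rank-deficient")
})

test_that("nonpositive signals are clamped with a warning count", {
  ph <- make_phantom()
  dwi <- stejskal_tanner(ph$field)
  dwi$signals[3, 2] <- 0
  dwi$signals[10, 5] <- -1
  expect_warning(fit_tensors_lls(dwi), "2 nonpositive")
})

test_that("noise is reproducible under a seed and differs across seeds", {
  ph <- make_phantom()
  f1 <- noisy_field(ph$field, snr = 15, seed = 3)
  f2 <- noisy_field(ph$field, snr = 15, seed = 3)
  f3 <- noisy_field(ph$field, snr = 15, seed = 4)
  expect_identical(f1$tensors, f2$tensors)
  expect_false(identical(f1$tensors, f3$tensors))
})
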