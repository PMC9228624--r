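test_that("ground truth generation is deterministic, sparse and exactly zero off-structure", {
  spec <- phantom_spec(image_size_px = 256, seed = 7)
  a <- generate_ground_truth(spec)
  b <- generate_ground_truth(spec)
  expect_identical(a$data, b$data)
  img <- a$data[, , 1]
  expect_true(all(img >= 0))
  expect_true(all(img %in% c(0, spec$filament_intensity)))
  expect_lt(mean(img > 0), 0.25)
  expect_gt(sum(img > 0), 0)
  # different seed gives a different field
  expect_false(identical(generate_ground_truth(phantom_spec(image_size_px = 256, seed = 8))$data,
                         a$data))
})

test_that("filament stroke width follows the physical width / pitch ratio", {
  # 63 nm filament on a 63 nm grid: single-pixel strokes. A straight stroke's
  # transverse cut has runs of exactly the stroke width.
  spec <- phantom_spec(image_size_px = 256, n_filaments = 1, curvature_scale = 0,
                       filament_width_nm = 63, pixel_pitch_nm = 63, seed = 3)
  img <- generate_ground_truth(spec)$data[, , 1]
  runs <- apply(img > 0, 2, function(col) {
    r <- rle(col)$lengths[rle(col)$values]
    if (length(r)) max(r) else NA_integer_
  })
  runs <- runs[!is.na(runs)]
  expect_true(length(runs) > 0)
  expect_lte(stats::median(runs), 2)  # 1 px wide, allowing near-vertical tangents
  # tripling the physical width triples the stroke
  spec3 <- phantom_spec(image_size_px = 256, n_filaments = 1, curvature_scale = 0,
                        filament_width_nm = 189, pixel_pitch_nm = 63, seed = 3)
  img3 <- generate_ground_truth(spec3)$data[, , 1]
  expect_gt(sum(img3 > 0), 2.5 * sum(img > 0))
})

test_that("zero filaments yields an all-zero image and bad parameters error", {
  img <- generate_ground_truth(phantom_spec(image_size_px = 128, n_filaments = 0))
  expect_true(all(img$data == 0))
  expect_error(phantom_spec(image_size_px = 2), "too small")
  expect_error(degradation_spec(noise_std = -1), "nonnegative")
})

test_that("identity degradation passes the image through unchanged", {
  truth <- generate_ground_truth(phantom_spec(image_size_px = 128, seed = 2))
  out <- degrade(truth, degradation_spec(blur_radius_nm = 0, noise_mean = 0,
                                         noise_std = 0))
  expect_equal(out$data, truth$data)
})

test_that("degradation is deterministic under a fixed seed", {
  truth <- generate_ground_truth(phantom_spec(image_size_px = 128, seed = 2))
  spec <- degradation_spec(270, 20, 4, seed = 9)
  expect_identical(degrade(truth, spec)$data, degrade(truth, spec)$data)
  spec2 <- degradation_spec(270, 20, 4, seed = 10)
  expect_false(identical(degrade(truth, spec2)$data, degrade(truth, spec)$data))
})

test_that("blur conserves total intensity when no clipping is active", {
  spec <- phantom_spec(image_size_px = 256, filament_intensity = 100, seed = 5)
  truth <- generate_ground_truth(spec)
  blurred <- degrade(truth, degradation_spec(blur_radius_nm = 270, noise_mean = 0,
                                             noise_std = 0))
  expect_lt(abs(sum(blurred$data) - sum(truth$data)) / sum(truth$data), 1e-3)
})

test_that("noise moments match the requested mean and STD on background", {
  zero <- image_stack(matrix(0, 200, 200), pitch_xy_nm = 63)
  # mean far enough from 0 that clipping is negligible
  out <- degrade(zero, degradation_spec(blur_radius_nm = 0, noise_mean = 40,
                                        noise_std = 10, seed = 4))
  n <- length(out$data)
  expect_lt(abs(mean(out$data) - 40), 5 * 10 / sqrt(n))
  expect_lt(abs(sd(out$data) - 10), 5 * 10 / sqrt(2 * n))
  # pure zero-mean noise: clipping at 0 halves the distribution but leaves
  # the positive tail intact, so the 97.5% quantile still sits at 1.96 STD
  out2 <- degrade(zero, degradation_spec(0, 0, 2, seed = 4))
  expect_lt(abs(quantile(out2$data, 0.975) - 1.96 * 2), 0.2)
})

test_that("noise mean lands on top of the blurred structure as specified", {
  truth <- generate_ground_truth(phantom_spec(image_size_px = 256, seed = 6))
  blurred <- degrade(truth, degradation_spec(270, 0, 0))
  noisy <- degrade(truth, degradation_spec(270, 40, 10, seed = 6))
  bg <- blurred$data < 1e-6  # far-from-structure pixels
  n <- sum(bg)
  delta <- mean(noisy$data[bg]) - mean(blurred$data[bg])
  expect_lt(abs(delta - 40), 3 * 10 / sqrt(n) + 0.1)
})
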