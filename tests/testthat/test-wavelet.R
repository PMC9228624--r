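# Frozen single-level coefficients for a seeded 32x32 normal field, computed
# with an independent reference implementation of the same filter bank
# (symmetric extension, expansive coefficient layout).
test_that("single-level coif3 coefficients match the independent reference", {
  set.seed(11)
  x <- matrix(rnorm(32 * 32), 32, 32)
  dec <- decompose(x, "coif3", 1L)
  expect_equal(dim(dec$approximation), c(24, 24))
  expect_equal(sum(dec$approximation), -24.905292401602, tolerance = 1e-9)
  expect_equal(dec$approximation[3, 5], 1.265521090784, tolerance = 1e-9)
  expect_equal(dec$approximation[10, 20], 0.461829474758, tolerance = 1e-9)
  expect_equal(sum(dec$details[[1]]$h), -2.820258248033, tolerance = 1e-9)
  expect_equal(dec$details[[1]]$h[3, 5], -0.258761589947, tolerance = 1e-9)
  expect_equal(sum(dec$details[[1]]$v), -30.605313640022, tolerance = 1e-9)
  expect_equal(dec$details[[1]]$v[10, 20], -0.111853651741, tolerance = 1e-9)
  expect_equal(sum(dec$details[[1]]$d), 2.114595761695, tolerance = 1e-9)
  expect_equal(dec$details[[1]]$d[3, 5], 0.654372945772, tolerance = 1e-9)
})

test_that("round trip is a perfect reconstruction for every supported family", {
  set.seed(21)
  x <- matrix(rnorm(96 * 128, sd = 50), 96, 128)
  for (w in c("haar", "db2", "coif3")) {
    lev <- if (w == "coif3") 2L else 4L
    dec <- decompose(x, w, lev)
    err <- max(abs(reconstruct(dec) - x)) / max(abs(x))
    expect_lt(err, 1e-8)
  }
})

test_that("a constant image lives entirely in the approximation band", {
  x <- matrix(42, 64, 64)
  dec <- decompose(x, "coif3", 2L)
  for (lev in dec$details) for (d in lev) expect_lt(max(abs(d)), 1e-9 * 42)
  expect_equal(mean(reconstruct(dec, levels = integer(0))), 42, tolerance = 1e-10)
})

test_that("coefficient pyramid sizes shrink dyadically with the filter margin", {
  x <- matrix(rnorm(256 * 256), 256, 256)
  dec <- decompose(x, "coif3", 3L)
  # expansive symmetric scheme: floor((n + 17) / 2) per level for coif3
  expect_equal(nrow(dec$details[[1]]$h), 136)
  expect_equal(nrow(dec$details[[2]]$h), 76)
  expect_equal(nrow(dec$details[[3]]$h), 46)
  expect_equal(dim(dec$approximation), c(46, 46))
})

test_that("band reconstruction plus its complement restores the image", {
  x <- blob_image(128, seed = 5)
  dec <- decompose(x, "coif3", 3L)
  band <- reconstruct_band(dec, band_selection(2, 3))
  complement <- reconstruct(dec, levels = 1L, keep_approximation = TRUE)
  expect_lt(max(abs(band + complement - x)) / max(abs(x)), 1e-8)
  # full range + approximation is the identity
  all_of_it <- reconstruct(dec, levels = 1:3, keep_approximation = TRUE)
  expect_lt(max(abs(all_of_it - x)) / max(abs(x)), 1e-8)
  # sub-band additivity: per-level reconstructions sum to the detail part
  per_level <- Reduce(`+`, lapply(1:3, function(n)
    reconstruct(dec, levels = n, keep_approximation = FALSE)))
  approx_only <- reconstruct(dec, levels = integer(0), keep_approximation = TRUE)
  expect_lt(max(abs(per_level + approx_only - x)) / max(abs(x)), 1e-6)
})

test_that("keeping only coarse detail levels strips white noise", {
  ratios <- sapply(1:5, function(s) {
    set.seed(s)
    noise <- matrix(rnorm(256 * 256), 256, 256)
    dec <- decompose(noise, "coif3", 6L)
    var(as.numeric(reconstruct_band(dec, band_selection(4, 6)))) / var(as.numeric(noise))
  })
  expect_true(all(ratios < 0.2))
})

test_that("band-limited energy of a bar concentrates at its dyadic scale", {
  for (w in c(4, 16, 32)) {
    img <- matrix(0, 256, 256)
    c0 <- 128 - floor(w / 2)
    img[, c0:(c0 + w - 1)] <- 100
    # soften the bar edges: a one-pixel blur removes the step discontinuity
    # whose broadband spectrum is not part of the bar's characteristic scale
    img <- sep_conv2_reflect_for_test(img)
    dec <- decompose(img, "coif3", 6L)
    e <- sapply(1:6, function(n)
      sum(reconstruct(dec, levels = n, keep_approximation = FALSE)^2))
    keep <- max(1, floor(log2(w))):min(6, ceiling(log2(w)) + 1)
    expect_gt(sum(e[keep]) / sum(e), 0.6)
  }
})

test_that("structure widths map to the expected level band", {
  b <- characteristic_band_for_width(16, 64)
  expect_equal(c(b$n_low, b$n_high), c(4L, 6L))
  b <- characteristic_band_for_width(20, 60)
  expect_equal(c(b$n_low, b$n_high), c(4L, 6L))
  b <- characteristic_band_for_width(1, 1)
  expect_equal(c(b$n_low, b$n_high), c(1L, 1L))
  expect_error(characteristic_band_for_width(0, 4), "width")
})

test_that("unknown wavelets and oversized bands are rejected", {
  expect_error(decompose(matrix(0, 32, 32), "sym9"), "supported")
  dec <- decompose(matrix(rnorm(64 * 64), 64, 64), "coif3", 1L)
  expect_error(reconstruct_band(dec, band_selection(1, 3)), "depth")
  # too-deep request degrades gracefully with a warning (the expansive
  # layout bottoms out once the approximation falls below the filter span)
  expect_warning(d2 <- decompose(matrix(rnorm(20 * 20), 20, 20), "coif3", 4L),
                 "reducing")
  expect_equal(d2$max_level, 2L)
})
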