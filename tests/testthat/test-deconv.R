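delta_kernel <- function() matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)

small_bar_mask <- function(n = 32, width = 7) {
  m <- matrix(0, n, n)
  c0 <- n / 2 - floor(width / 2)
  m[5:(n - 4), c0:(c0 + width - 1)] <- 1
  m
}

test_that("a delta PSF makes the multiplicative update a no-op", {
  obs <- small_bar_mask()
  mid <- lr_step(obs, obs, delta_kernel())
  expect_equal(mid, obs, tolerance = 1e-12)
  # and the full driver returns the mask unchanged for any iteration count
  m <- optical_model()
  expect_warning(
    out <- lr_deconvolve(obs, m, lr_config(k_max = 5, xi = 1e-6), pitch_nm = 1e9),
    "delta")
  expect_equal(out, obs, tolerance = 1e-10)
})

test_that("a flat image is a fixed point of the update", {
  obs <- matrix(3, 24, 24)
  est <- matrix(3, 24, 24)
  psf <- make_psf_2d(optical_model(xi = 2.5), pitch_nm = 200)
  mid <- lr_step(est, obs, psf)
  expect_equal(mid, obs, tolerance = 1e-9)
})

test_that("update inputs are validated", {
  obs <- small_bar_mask()
  expect_error(lr_step(obs, obs, matrix(1, 3, 3)), "normalized")
  expect_error(lr_step(obs - 2, obs, delta_kernel()), "nonnegative")
})

test_that("acceleration factor matches the direct inner-product formula", {
  set.seed(41)
  for (rep in 1:10) {
    a <- matrix(rnorm(36), 6, 6); b <- matrix(rnorm(36), 6, 6); c <- matrix(rnorm(36), 6, 6)
    num <- sum((a - b) * (b - c)); den <- sum((b - c)^2)
    expect_equal(acceleration_factor(a, b, c, clamp = FALSE), num / den,
                 tolerance = 1e-12)
  }
  z <- matrix(1, 4, 4)
  expect_equal(acceleration_factor(z + 1, z, z), 0)           # stalled iterate
  expect_equal(acceleration_factor(z, z, z), 0)               # first-iteration convention
  # forced unit factor is clamped strictly below 1
  prev <- matrix(0, 4, 4); cur <- matrix(1, 4, 4); mid <- matrix(2, 4, 4)
  expect_lt(acceleration_factor(mid, cur, prev), 1)
  expect_gte(acceleration_factor(mid, cur, prev), 0)
})

test_that("undamped unaccelerated deconvolution equals the textbook algorithm", {
  obs <- small_bar_mask(32, 7)
  model <- optical_model(xi = 2.5)
  pitch <- 100  # sigma ~ 7 px at this pitch: modest kernel on a 32px field
  cfg <- lr_config(k_max = 4, damping = 0, xi = 2.5, accelerate = FALSE)
  mine <- lr_deconvolve(obs, model, cfg, pitch_nm = pitch)
  psf <- make_psf_2d(model, pitch)
  ref <- rl_textbook(obs, psf, 4)
  expect_lt(max(abs(mine - ref)), 1e-8)
})

test_that("iterates stay nonnegative and conserve flux on interior fixtures", {
  obs <- small_bar_mask(48, 5)
  model <- optical_model(xi = 2.5)
  cfg <- lr_config(k_max = 8, damping = 0, accelerate = FALSE)
  out <- lr_deconvolve(obs, model, cfg, pitch_nm = 150)
  expect_true(all(out >= 0))
  expect_lt(abs(sum(out) - sum(obs)) / sum(obs), 0.01)
})

test_that("deconvolving a blurred bar reduces the error to the true bar", {
  n <- 48
  bar <- matrix(0, n, n); bar[, 21:27] <- 1
  model <- optical_model(xi = 2.5)
  psf <- make_psf_2d(model, pitch_nm = 150)
  blurred <- conv2_direct(bar, psf)
  cfg <- lr_config(k_max = 10, damping = 0, accelerate = FALSE)
  out <- lr_deconvolve(blurred, model, cfg, pitch_nm = 150)
  rmse <- function(x) sqrt(mean((x - bar)^2))
  expect_lt(rmse(out), rmse(blurred))
})

test_that("defaults shrink a thick outline toward its skeleton", {
  obs <- small_bar_mask(64, 9)
  model <- optical_model()
  out <- lr_deconvolve(obs, model, lr_config(), pitch_nm = 63)
  area_in <- sum(obs)
  area_out <- sum(out >= 1)
  expect_gt(area_out, 0)
  expect_lt(area_out, area_in)
  expect_true(all(out >= 0))
})

test_that("an undersized PSF fragments the skeleton where the matched one keeps it whole", {
  # filament-network mask: three crossing thick strokes
  n <- 96
  m <- matrix(0, n, n)
  m[44:52, 8:88] <- 1
  m[8:88, 44:52] <- 1
  for (i in 12:84) m[i, pmax(1, pmin(n, (i - 3):(i + 3)))] <- 1
  model <- optical_model()
  frag <- function(xi) {
    out <- lr_deconvolve(m, model, lr_config(xi = xi), pitch_nm = 63)
    n_components(1 * (out >= 1))
  }
  expect_gt(frag(0.5), frag(2.5))
})

test_that("empty masks and runaway growth are hard errors", {
  expect_error(lr_deconvolve(matrix(0, 16, 16), optical_model(), lr_config(),
                             pitch_nm = 63), "empty structure")
})

test_that("deconvolution trace reports iteration diagnostics", {
  obs <- small_bar_mask(32, 7)
  out <- lr_deconvolve(obs, optical_model(), lr_config(k_max = 3),
                       pitch_nm = 150, trace = TRUE)
  tr <- attr(out, "trace")
  expect_equal(nrow(tr), 3)
  expect_true(all(c("iteration", "f", "total", "area_ge_1") %in% names(tr)))
  expect_true(all(tr$f >= 0 & tr$f < 1))
})
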