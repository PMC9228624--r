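#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(\mathrm{MAX}^2 / \mathrm{MSE})} in decibels, with MAX
#' defaulting to the working intensity ceiling 255. Identical images have
#' zero MSE and are reported as \code{Inf}.
#'
#' @param reference,test Numeric matrices (or arrays) of equal shape.
#' @param max_value Peak intensity value (default 255).
#' @return PSNR in dB (\code{Inf} for identical inputs).
#' @examples
#' a <- matrix(0, 8, 8)
#' psnr(a, a + 40)  # 10*log10(255^2/1600) = 16.088
#' @export
psnr <- function(reference, test, max_value = intensity_max()) {
  if (!all(dim(reference) == dim(test))) stopf("shape mismatch")
  if (max_value <= 0) stopf("max_value must be positive")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

# 11x11 Gaussian window, sigma 1.5, normalized (the standard SSIM window)
ssim_window <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1L) %/% 2L
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  w <- outer(k, k)
  w / sum(w)
}

#' Structural similarity index (mean SSIM)
#'
#' Mean local structural similarity over an 11x11 Gaussian window (sigma
#' 1.5), with stabilizers \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2}.
#' Local statistics use valid windows only (no padding), as in the original
#' formulation.
#'
#' The dynamic range \eqn{L} defaults to 1 even though intensities live on
#' the 0-255 working scale. This is deliberate and matches the widespread
#' convention for double-valued images: with near-zero stabilizers relative
#' to the data scale, SSIM on a dark background is driven by the actual
#' noise structure rather than being absorbed by the constants, which is the
#' regime in which additive background noise on a sparse filament field
#' scores the characteristically poor values (below 0.1) and a clean
#' extraction scores high. Set \code{dynamic_range = max} of your data for
#' the strictly scale-matched variant.
#'
#' @param reference,test Numeric matrices of equal shape, sides >= 11.
#' @param dynamic_range Stabilizer scale \eqn{L} (default 1; see Details).
#' @return Mean SSIM, a number in [-1, 1].
#' @export
ssim <- function(reference, test, dynamic_range = 1) {
  if (!all(dim(reference) == dim(test))) stopf("shape mismatch")
  w <- ssim_window()
  if (any(dim(reference) < dim(w))) stopf("image smaller than the 11x11 SSIM window")
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  k1 <- w[, 6]  # separable: outer(k, k) with k normalized columnwise
  k1 <- k1 / sum(k1)
  f <- function(m) {
    r <- sep_conv2_reflect(m, k1)
    r[6:(nrow(m) - 5), 6:(ncol(m) - 5), drop = FALSE]  # valid region
  }
  mu1 <- f(reference); mu2 <- f(test)
  s11 <- f(reference^2) - mu1^2
  s22 <- f(test^2) - mu2^2
  s12 <- f(reference * test) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Intensity line profile
#'
#' Extracts a row profile (optionally restricted to a column range) from a
#' matrix or single-slice stack, with physical positions attached.
#'
#' @param image A numeric matrix or \code{\link{image_stack}} slice.
#' @param row Row index.
#' @param cols Optional integer range of columns (default: all).
#' @param pitch_nm Pixel pitch in nm (taken from the stack if one is given).
#' @return An object of class \code{line_profile}: list with
#'   \code{positions_nm} (increasing) and \code{intensities}.
#' @export
line_profile <- function(image, row, cols = NULL, pitch_nm = NULL) {
  if (inherits(image, "image_stack")) {
    if (is.null(pitch_nm)) pitch_nm <- image$pitch_xy_nm
    image <- get_slice(image, 1)
  }
  if (is.null(pitch_nm)) stopf("pitch_nm required for a bare matrix")
  if (is.null(cols)) cols <- seq_len(ncol(image))
  structure(list(positions_nm = (cols - 1) * pitch_nm,
                 intensities = image[row, cols]),
            class = "line_profile")
}

#' Full width at half maximum of a line profile
#'
#' Measures the width between the two half-maximum crossings bracketing the
#' profile peak, each located by linear interpolation between adjacent
#' samples. By default the background level is taken as zero (profiles come
#' from masked, background-free images), so half-maximum is peak/2 and the
#' result is invariant to uniform intensity scaling; for raw profiles riding
#' on an offset background, \code{baseline = "min"} measures the half
#' maximum of the peak above the profile minimum instead. If the profile
#' does not cross half-maximum on both sides of the peak (e.g. a monotone
#' ramp), the width is undefined and \code{NA} is returned with a warning.
#'
#' @param profile A \code{\link{line_profile}}, or a numeric vector of
#'   intensities (then \code{pitch_nm} gives the sample spacing).
#' @param pitch_nm Sample spacing in nm when \code{profile} is a bare vector.
#' @param baseline Background convention: \code{"zero"} (default) or
#'   \code{"min"} (profile minimum).
#' @return FWHM in nm, or \code{NA_real_} if undefined.
#' @export
fwhm <- function(profile, pitch_nm = NULL, baseline = c("zero", "min")) {
  baseline <- match.arg(baseline)
  if (inherits(profile, "line_profile")) {
    pos <- profile$positions_nm
    y <- profile$intensities
  } else {
    if (is.null(pitch_nm)) stopf("pitch_nm required for a bare vector")
    y <- as.numeric(profile)
    pos <- (seq_along(y) - 1) * pitch_nm
  }
  n <- length(y)
  base <- if (baseline == "min") min(y) else 0
  y <- y - base
  p <- which.max(y)
  half <- y[p] / 2
  if (y[p] <= 0) { warnf("profile has no positive peak; FWHM undefined"); return(NA_real_) }
  cross <- function(i0, i1) {
    # linear interpolation of the half-max crossing between samples i0, i1
    pos[i0] + (half - y[i0]) * (pos[i1] - pos[i0]) / (y[i1] - y[i0])
  }
  left <- NA_real_
  if (p > 1)
    for (i in seq(p, 2)) if (y[i - 1] < half && y[i] >= half) { left <- cross(i - 1, i); break }
  right <- NA_real_
  if (p < n)
    for (i in p:(n - 1)) if (y[i] >= half && y[i + 1] < half) { right <- cross(i, i + 1); break }
  if (is.na(left) || is.na(right)) {
    warnf("profile does not cross half-maximum on both sides of the peak; FWHM undefined")
    return(NA_real_)
  }
  right - left
}
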