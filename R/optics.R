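#' Optical model of the confocal imaging system
#'
#' Bundles the optical parameters from which the pipeline derives its Gaussian
#' radii. The lateral radius is the diffraction-limited Gaussian radius
#' \eqn{r_\perp = 0.61\,\lambda_e / NA} and the axial radius is
#' \eqn{r_\parallel = 4 n \lambda_e / (2\,NA^2)}, both in nanometres. The
#' deconvolution PSF width is \eqn{\Delta r = \xi\, r_\perp}, where \eqn{\xi}
#' is an empirical coefficient tuned by numerical experiment (see
#' \code{\link{lr_deconvolve}}).
#'
#' @param numerical_aperture Numerical aperture of the objective (default 1.4,
#'   a 100x oil-immersion lens).
#' @param excitation_wavelength_nm Excitation wavelength in nm (default 640).
#' @param refractive_index Immersion-medium refractive index (default 1.515,
#'   standard immersion oil).
#' @param xi Empirical PSF-width coefficient \eqn{\xi} for deconvolution
#'   (default 2.5).
#' @return An object of class \code{optical_model}.
#' @examples
#' m <- optical_model()
#' lateral_radius(m)   # ~278.9 nm
#' axial_radius(m)     # ~989.4 nm
#' @export
optical_model <- function(numerical_aperture = 1.4,
                          excitation_wavelength_nm = 640,
                          refractive_index = 1.515,
                          xi = 2.5) {
  if (numerical_aperture <= 0) stopf("numerical_aperture must be positive")
  if (excitation_wavelength_nm <= 0) stopf("excitation_wavelength_nm must be positive")
  if (refractive_index <= 0) stopf("refractive_index must be positive")
  if (xi <= 0) stopf("xi must be positive")
  structure(list(numerical_aperture = numerical_aperture,
                 excitation_wavelength_nm = excitation_wavelength_nm,
                 refractive_index = refractive_index,
                 xi = xi),
            class = "optical_model")
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model: NA", x$numerical_aperture,
      " lambda_e", x$excitation_wavelength_nm, "nm",
      " n", x$refractive_index, " xi", x$xi, "\n")
  cat("  r_lateral ", format(lateral_radius(x)), "nm;  r_axial ",
      format(axial_radius(x)), "nm;  delta_r ", format(deconv_radius(x)), "nm\n")
  invisible(x)
}

#' Lateral Gaussian radius of the system
#'
#' \eqn{r_\perp = 0.61\,\lambda_e / NA}, in nanometres.
#' @param model An \code{\link{optical_model}}.
#' @return Lateral radius in nm.
#' @export
lateral_radius <- function(model) {
  0.61 * model$excitation_wavelength_nm / model$numerical_aperture
}

#' Axial Gaussian radius of the system
#'
#' \eqn{r_\parallel = 4 n \lambda_e / (2\,NA^2)}, in nanometres.
#' @param model An \code{\link{optical_model}}.
#' @return Axial radius in nm.
#' @export
axial_radius <- function(model) {
  4 * model$refractive_index * model$excitation_wavelength_nm /
    (2 * model$numerical_aperture^2)
}

#' Deconvolution PSF radius
#'
#' \eqn{\Delta r = \xi\, r_\perp}: the Gaussian radius actually used for
#' Richardson-Lucy deconvolution of the binary outline. The outline produced
#' by scale-band extraction and thresholding is broader than the optical PSF,
#' hence \eqn{\xi > 1} in practice.
#' @param model An \code{\link{optical_model}}.
#' @return PSF radius in nm.
#' @export
deconv_radius <- function(model) model$xi * lateral_radius(model)

#' Isotropic 2D Gaussian PSF kernel
#'
#' Builds the discrete point spread function used by the deconvolution stage:
#' an isotropic 2D Gaussian with standard deviation \eqn{\Delta r / \mathrm{pitch}}
#' pixels, truncated at \code{truncation_sigmas}, with odd side length and
#' normalized to sum to one.
#'
#' @param model An \code{\link{optical_model}}.
#' @param pitch_nm Pixel pitch of the image grid in nm.
#' @param truncation_sigmas Kernel support half-width in standard deviations
#'   (default 3).
#' @return A numeric matrix of odd side length summing to 1.
#' @export
make_psf_2d <- function(model, pitch_nm, truncation_sigmas = 3) {
  if (pitch_nm <= 0) stopf("pitch_nm must be positive")
  dr <- deconv_radius(model)
  if (dr < pitch_nm / 4)
    warnf("PSF radius %.3g nm is below pitch/4 (%.3g nm); kernel degenerates toward a delta",
          dr, pitch_nm / 4)
  sigma <- dr / pitch_nm
  k1 <- gauss_kernel_1d(sigma, truncation_sigmas)
  k <- outer(k1, k1)
  k / sum(k)
}

#' Fluorescence image stack
#'
#' Container for a z-stack of nonnegative intensities with its grid metadata.
#' Data are stored as a 3D array indexed \code{[y, x, z]}; a 2D matrix is
#' accepted and treated as a single slice. Every resampling operation updates
#' the pitch metadata consistently.
#'
#' @param data 2D matrix or 3D array of finite, nonnegative intensities.
#' @param pitch_xy_nm Lateral pixel pitch in nm.
#' @param pitch_z_nm Axial slice interval in nm (default equal to the lateral
#'   pitch, irrelevant for single-slice stacks).
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(data, pitch_xy_nm, pitch_z_nm = pitch_xy_nm) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("data must be a 2D matrix or 3D array")
  if (any(!is.finite(data))) stopf("intensities must be finite")
  if (any(data < 0)) stopf("intensities must be nonnegative")
  if (pitch_xy_nm <= 0 || pitch_z_nm <= 0) stopf("pitches must be positive")
  structure(list(data = data, pitch_xy_nm = pitch_xy_nm, pitch_z_nm = pitch_z_nm),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack: %d x %d pixels, %d slice(s); pitch %.4g nm (xy), %.4g nm (z)\n",
              d[1], d[2], d[3], x$pitch_xy_nm, x$pitch_z_nm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

n_slices <- function(stack) dim(stack$data)[3]
get_slice <- function(stack, i) stack$data[, , i]

# Row-normalized Gaussian interpolation weight matrix for one axis.
# n_in samples at spacing `pitch`; n_out = n_in * factor samples at spacing
# pitch/factor, sharing the origin so every factor-th output sample coincides
# with an input sample. Weights exp(-d^2 / (2 radius^2)) truncated at
# 3 radii (at least the nearest sample is always kept).
interp_weights_1d <- function(n_in, factor, pitch, radius) {
  if (factor == 1L) return(diag(n_in))
  n_out <- n_in * factor
  u <- (seq_len(n_out) - 1) / factor      # output position, input-index units
  i <- seq_len(n_in) - 1
  d <- outer(u, i, "-") * pitch
  w <- exp(-d^2 / (2 * radius^2))
  w[abs(d) > 3 * radius] <- 0
  # guard: keep nearest neighbour when truncation empties a row
  empty <- rowSums(w) == 0
  if (any(empty)) {
    nearest <- pmin(pmax(round(u[empty]) + 1, 1), n_in)
    w[cbind(which(empty), nearest)] <- 1
  }
  w / rowSums(w)
}

#' Expand a stack onto a finer grid by Gaussian interpolation
#'
#' Resamples the stack onto a grid refined by integer factors, assigning each
#' output voxel the Gaussian-weight normalized average of the input samples:
#' lateral distances are weighted with radius \eqn{r_\perp} and axial
#' distances with radius \eqn{r_\parallel}, evaluated at physical (nm)
#' distances and truncated at 3 radii. Because the weight is separable and
#' the normalization factorizes over axes, the interpolation is applied as
#' three successive 1D passes. Output pitches are the input pitches divided
#' by the factors. Values are convex combinations of input samples, so the
#' output never overshoots the input range. A factor of 1 on an axis leaves
#' that axis untouched.
#'
#' @param stack An \code{\link{image_stack}}.
#' @param factor_xy Integer lateral refinement factor (>= 1); 512 becomes
#'   512 * factor_xy pixels per side.
#' @param factor_z Integer axial refinement factor (>= 1).
#' @param model An \code{\link{optical_model}} supplying the radii.
#' @return A new \code{\link{image_stack}} on the finer grid.
#' @examples
#' s <- image_stack(matrix(runif(64), 8, 8), pitch_xy_nm = 250)
#' e <- expand_stack(s, 4, 1, optical_model())
#' e$pitch_xy_nm  # 62.5
#' @export
expand_stack <- function(stack, factor_xy, factor_z = 1L, model = optical_model()) {
  if (length(stack$data) == 0) stopf("empty stack")
  factor_xy <- as.integer(factor_xy); factor_z <- as.integer(factor_z)
  if (factor_xy < 1L || factor_z < 1L) stopf("expansion factors must be >= 1")
  if (factor_xy == 1L && factor_z == 1L) return(stack)
  d <- dim(stack$data)
  rl <- lateral_radius(model); ra <- axial_radius(model)
  wy <- interp_weights_1d(d[1], factor_xy, stack$pitch_xy_nm, rl)
  wx <- interp_weights_1d(d[2], factor_xy, stack$pitch_xy_nm, rl)
  nz_out <- d[3] * factor_z
  out <- array(0, dim = c(d[1] * factor_xy, d[2] * factor_xy, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- wy %*% stack$data[, , k] %*% t(wx)
  if (factor_z > 1L) {
    wz <- interp_weights_1d(d[3], factor_z, stack$pitch_z_nm, ra)
    flat <- matrix(out, nrow = prod(dim(out)[1:2]), ncol = d[3])
    out <- array(flat %*% t(wz), dim = c(dim(out)[1:2], nz_out))
  }
  image_stack(out,
              pitch_xy_nm = stack$pitch_xy_nm / factor_xy,
              pitch_z_nm = stack$pitch_z_nm / factor_z)
}
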