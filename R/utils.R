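# Internal numerical helpers shared across the pipeline stages.

# Working intensity scale: images are held as floating point on an
# 8-bit-equivalent range [0, 255]. Centralized so metrics, clipping and the
# phantom generator agree on one peak value.
.INTENSITY_MAX <- 255

#' Working intensity ceiling
#'
#' The package stores images as floating point on an 8-bit-equivalent scale.
#' This returns the peak value (255) used for clipping after degradation and
#' as the default PSNR peak.
#' @return A single number, 255.
#' @export
intensity_max <- function() .INTENSITY_MAX

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Reflective (mirror, edge value not repeated twice beyond the border in the
# half-sample sense: c(h:1, 1:n, n:(n-h+1))) padding of a matrix by `h` rows
# and `w` cols. h/w must not exceed the corresponding dimension.
reflect_pad <- function(m, h, w = h) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (h > n1 || w > n2) stopf("padding (%d, %d) exceeds image size (%d, %d)", h, w, n1, n2)
  ri <- c(if (h > 0) h:1, 1:n1, if (h > 0) n1:(n1 - h + 1))
  ci <- c(if (w > 0) w:1, 1:n2, if (w > 0) n2:(n2 - w + 1))
  m[ri, ci, drop = FALSE]
}

# 1D convolution of every column of `m` with kernel `k` (odd length),
# 'same' output size, reflective boundary.
conv_cols_reflect <- function(m, k) {
  lk <- length(k)
  h <- (lk - 1L) %/% 2L
  if (h == 0L) return(m * k)
  p <- reflect_pad(m, h, 0L)
  n <- nrow(m)
  out <- 0
  for (j in seq_len(lk)) out <- out + k[j] * p[(lk - j) + seq_len(n), , drop = FALSE]
  out
}

# Separable 2D convolution with reflective boundaries: kernel = ky %o% kx.
sep_conv2_reflect <- function(m, ky, kx = ky) {
  t(conv_cols_reflect(t(conv_cols_reflect(m, ky)), kx))
}

# Normalized 1D Gaussian kernel, truncated at `trunc` sigmas, odd length.
gauss_kernel_1d <- function(sigma, trunc = 3) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(trunc * sigma))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# FFT 2D convolution plan with reflective boundary handling.
# Returns a function(img) -> img convolved with `kernel` ('same' size).
# The kernel OTF is computed once; repeated application (Richardson-Lucy
# iterations) reuses it. Kernel must have odd dimensions.
fft_conv2_plan <- function(img_dim, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  n1 <- img_dim[1]; n2 <- img_dim[2]
  # pad to a 2-3-5-smooth size for fast mixed-radix FFTs
  N1 <- stats::nextn(n1 + 2L * kh, c(2, 3, 5))
  N2 <- stats::nextn(n2 + 2L * kw, c(2, 3, 5))
  kp <- matrix(0, N1, N2)
  kp[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  # center the kernel at (1,1) so convolution output is unshifted
  kp <- kp[c((kh + 1):N1, if (kh > 0) 1:kh), c((kw + 1):N2, if (kw > 0) 1:kw)]
  otf <- stats::fft(kp)
  function(img) {
    p <- reflect_pad(img, kh, kw)
    xp <- matrix(0, N1, N2)
    xp[seq_len(nrow(p)), seq_len(ncol(p))] <- p
    y <- Re(stats::fft(stats::fft(xp) * otf, inverse = TRUE)) / (N1 * N2)
    y[kh + seq_len(n1), kw + seq_len(n2), drop = FALSE]
  }
}

clip01 <- function(x, lo = 0, hi = .INTENSITY_MAX) pmin(pmax(x, lo), hi)
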