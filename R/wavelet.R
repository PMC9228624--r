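# Multi-level separable 2D discrete wavelet analysis (Mallat pyramid) with
# half-sample symmetric boundary extension. The decimated transform keeps
# floor((n + L - 1)/2) coefficients per axis and level (L = filter length),
# i.e. the usual slightly expansive symmetric-extension scheme, which gives
# exact perfect reconstruction for arbitrary image sizes.

# Orthogonal filter banks (analysis low/high pass). Synthesis filters are the
# time-reversed analysis filters.
.wavelet_filters <- list(
  haar = list(lo = c(0.7071067811865476, 0.7071067811865476),
              hi = c(-0.7071067811865476, 0.7071067811865476)),
  db2 = list(lo = c(-0.12940952255126037, 0.2241438680420134,
                    0.8365163037378079, 0.48296291314453416),
             hi = c(-0.48296291314453416, 0.8365163037378079,
                    -0.2241438680420134, -0.12940952255126037)),
  coif3 = list(lo = c(-3.459977283621256e-05, -7.098330313814125e-05,
                      4.662169601128863e-04, 1.117518770891146e-03,
                      -2.574517688750142e-03, -9.007976136662066e-03,
                      1.588054486362016e-02, 3.455502757306163e-02,
                      -8.230192710688598e-02, -7.179982161931202e-02,
                      4.284834763776168e-01, 7.937772226256206e-01,
                      4.051769024096169e-01, -6.112339000267287e-02,
                      -6.577191128186851e-02, 2.345269614184190e-02,
                      7.782596427325418e-03, -3.793512864491014e-03),
               hi = c(3.793512864491014e-03, 7.782596427325418e-03,
                      -2.345269614184190e-02, -6.577191128186851e-02,
                      6.112339000267287e-02, 4.051769024096169e-01,
                      -7.937772226256206e-01, 4.284834763776168e-01,
                      7.179982161931202e-02, -8.230192710688598e-02,
                      -3.455502757306163e-02, 1.588054486362016e-02,
                      9.007976136662066e-03, -2.574517688750142e-03,
                      -1.117518770891146e-03, 4.662169601128863e-04,
                      7.098330313814125e-05, -3.459977283621256e-05))
)

wavelet_filter_pair <- function(name) {
  f <- .wavelet_filters[[name]]
  if (is.null(f))
    stopf("unknown wavelet '%s'; supported: %s", name,
          paste(names(.wavelet_filters), collapse = ", "))
  f
}

# -- 1D analysis/synthesis applied to all columns of a matrix ---------------

# Symmetric-pad rows by L-1, full convolution with `filt`, dyadic
# downsample; output has floor((n + L - 1)/2) rows.
dwt_step_cols <- function(m, filt) {
  lf <- length(filt); n <- nrow(m)
  if (n < lf) stopf("signal shorter than filter")
  p <- m[c((lf - 1):1, 1:n, n:(n - lf + 2)), , drop = FALSE]
  L <- (n + lf - 1L) %/% 2L
  # full convolution sampled at rows lf + 1, lf + 3, ... of the result
  out <- matrix(0, L, ncol(m))
  base <- lf + seq(1L, by = 2L, length.out = L)   # 1-based conv index
  for (j in seq_len(lf))
    out <- out + filt[j] * p[base - j + 1L, , drop = FALSE]
  out
}

# Inverse of one level: upsample both coefficient bands, convolve with the
# time-reversed filters, sum, crop the filter transient, trim to out_len.
idwt_step_cols <- function(a, d, lo, hi, out_len) {
  lf <- length(lo); L <- nrow(a)
  rec_lo <- rev(lo); rec_hi <- rev(hi)
  up <- function(cf) {
    u <- matrix(0, 2L * L - 1L, ncol(cf))
    u[seq(1L, by = 2L, length.out = L), ] <- cf
    u
  }
  ua <- up(a); ud <- up(d)
  nfull <- nrow(ua) + lf - 1L
  y <- matrix(0, nfull, ncol(a))
  for (j in seq_len(lf)) {
    idx <- seq_len(nrow(ua)) + j - 1L
    y[idx, ] <- y[idx, ] + rec_lo[j] * ua + rec_hi[j] * ud
  }
  y <- y[(lf - 1L):(nfull - lf + 2L), , drop = FALSE]
  y[seq_len(out_len), , drop = FALSE]
}

dwt2_step <- function(m, filt) {
  # columns (y) first, then rows (x)
  lo_y <- dwt_step_cols(m, filt$lo)
  hi_y <- dwt_step_cols(m, filt$hi)
  list(ll = t(dwt_step_cols(t(lo_y), filt$lo)),
       lh = t(dwt_step_cols(t(lo_y), filt$hi)),   # detail along x
       hl = t(dwt_step_cols(t(hi_y), filt$lo)),   # detail along y
       hh = t(dwt_step_cols(t(hi_y), filt$hi)))   # diagonal detail
}

idwt2_step <- function(ll, lh, hl, hh, filt, out_dim) {
  mid_rows <- nrow(ll)
  lo_y <- t(idwt_step_cols(t(ll), t(lh), filt$lo, filt$hi, out_dim[2]))
  hi_y <- t(idwt_step_cols(t(hl), t(hh), filt$lo, filt$hi, out_dim[2]))
  idwt_step_cols(lo_y, hi_y, filt$lo, filt$hi, out_dim[1])
}

# -- public surface ---------------------------------------------------------

#' Multi-level 2D discrete wavelet decomposition
#'
#' Decomposes an image with the separable Mallat pyramid: at each level the
#' current approximation is filtered by the low/high-pass pair along both
#' axes and dyadically downsampled, yielding one approximation and three
#' oriented detail sub-bands (horizontal, vertical, diagonal) per level.
#' Boundary handling is half-sample symmetric extension. If the deepest
#' approximation would become shorter than the filter, the level count is
#' reduced with a warning.
#'
#' @param image A numeric matrix.
#' @param wavelet Wavelet family name: \code{"coif3"} (default),
#'   \code{"db2"} or \code{"haar"}.
#' @param max_level Number of pyramid levels (default 6).
#' @return An object of class \code{wavelet_decomposition} with elements
#'   \code{approximation} (deepest-level low-pass), \code{details} (a list,
#'   one per level, each with matrices \code{h}, \code{v}, \code{d}),
#'   \code{dims} (the per-level input sizes needed for reconstruction),
#'   \code{wavelet} and \code{max_level}.
#' @seealso \code{\link{reconstruct}}, \code{\link{reconstruct_band}}
#' @export
decompose <- function(image, wavelet = "coif3", max_level = 6L) {
  stopifnot(is.matrix(image))
  filt <- wavelet_filter_pair(wavelet)
  lf <- length(filt$lo)
  max_level <- as.integer(max_level)
  if (max_level < 1L) stopf("max_level must be >= 1")
  # depth at which coefficient matrices would fall below the filter support
  dims <- list(); details <- vector("list", max_level)
  cur <- image; lev <- 0L
  for (n in seq_len(max_level)) {
    if (min(dim(cur)) < lf) {
      warnf("image supports only %d level(s) for '%s'; reducing from %d",
            lev, wavelet, max_level)
      break
    }
    dims[[n]] <- dim(cur)
    s <- dwt2_step(cur, filt)
    details[[n]] <- list(h = s$lh, v = s$hl, d = s$hh)
    cur <- s$ll
    lev <- n
  }
  if (lev == 0L) stopf("image too small for even one '%s' level", wavelet)
  structure(list(approximation = cur,
                 details = details[seq_len(lev)],
                 dims = dims[seq_len(lev)],
                 wavelet = wavelet,
                 max_level = lev),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("Wavelet decomposition: '%s', %d level(s); approximation %d x %d\n",
              x$wavelet, x$max_level, nrow(x$approximation), ncol(x$approximation)))
  invisible(x)
}

#' Detail-scale band selection
#'
#' Chooses the range of decomposition levels whose detail sub-bands are kept
#' by \code{\link{reconstruct_band}}. Level n captures structure of
#' characteristic size roughly \eqn{2^n} pixels.
#'
#' @param n_low,n_high Lower and upper level bounds, \code{1 <= n_low <=
#'   n_high}.
#' @return An object of class \code{band_selection}.
#' @export
band_selection <- function(n_low = 4L, n_high = 6L) {
  n_low <- as.integer(n_low); n_high <- as.integer(n_high)
  if (n_low < 1L || n_high < n_low) stopf("need 1 <= n_low <= n_high")
  structure(list(n_low = n_low, n_high = n_high), class = "band_selection")
}

#' Band selection for a structure width range
#'
#' Maps a characteristic structure width range (in pixels) to decomposition
#' levels: \code{n_low = floor(log2(width_min))}, \code{n_high =
#' ceil(log2(width_max))}, clamped to \code{[1, max_level]}. A width range of
#' 16 to 64 pixels maps to levels 4 to 6.
#'
#' @param width_px_min,width_px_max Positive structure widths in pixels.
#' @param max_level Upper clamp (default 6).
#' @return A \code{\link{band_selection}}.
#' @export
characteristic_band_for_width <- function(width_px_min, width_px_max,
                                          max_level = 6L) {
  if (width_px_min <= 0 || width_px_max < width_px_min)
    stopf("need 0 < width_px_min <= width_px_max")
  lo <- max(1L, min(as.integer(max_level), as.integer(floor(log2(width_px_min)))))
  hi <- max(1L, min(as.integer(max_level), as.integer(ceiling(log2(width_px_max)))))
  band_selection(lo, max(lo, hi))
}

#' Inverse wavelet transform
#'
#' Reconstructs the image from a decomposition, optionally restricted to a
#' subset of detail levels and/or without the deepest approximation. An
#' unrestricted reconstruction reproduces the input to floating-point
#' accuracy (perfect reconstruction).
#'
#' @param dec A \code{\link{wavelet_decomposition}}.
#' @param levels Integer vector of detail levels to keep (default: all).
#' @param keep_approximation Keep the deepest approximation band (default
#'   TRUE).
#' @return A numeric matrix of the original image size.
#' @export
reconstruct <- function(dec, levels = seq_len(dec$max_level),
                        keep_approximation = TRUE) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  filt <- wavelet_filter_pair(dec$wavelet)
  cur <- if (keep_approximation) dec$approximation else
    array(0, dim = dim(dec$approximation))
  for (n in rev(seq_len(dec$max_level))) {
    det <- dec$details[[n]]
    if (!(n %in% levels)) det <- lapply(det, function(m) array(0, dim = dim(m)))
    cur <- idwt2_step(cur, det$h, det$v, det$d, filt, dec$dims[[n]])
  }
  cur
}

#' Scale-band extraction
#'
#' Reconstructs only the detail sub-bands of levels \code{n_low..n_high},
#' discarding the approximation (slow illumination background) and all other
#' detail levels (mostly pixel-scale noise): the scale-limited structure
#' image from which the binary outline is extracted. The complement (input
#' minus result) is the discarded component.
#'
#' @param dec A \code{\link{wavelet_decomposition}}.
#' @param band A \code{\link{band_selection}}.
#' @return A numeric matrix of the original image size (oscillating around
#'   zero; clip at zero before intensity thresholding).
#' @export
reconstruct_band <- function(dec, band = band_selection()) {
  stopifnot(inherits(band, "band_selection"))
  if (band$n_high > dec$max_level)
    stopf("band upper level %d exceeds decomposition depth %d",
          band$n_high, dec$max_level)
  reconstruct(dec, levels = band$n_low:band$n_high, keep_approximation = FALSE)
}
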