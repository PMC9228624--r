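# TIFF I/O. The tiff package exchanges pixel data normalized to [0, 1], so
# intensities are mapped through a scale factor: float pages are stored as
# value / scale and integer pages are restored to their native integer range.

#' Read a (multi-page) TIFF into an image stack
#'
#' Accepts 8/16-bit integer or 32-bit float TIFFs. Integer pages are restored
#' to their native range (the normalized values are multiplied by
#' \code{2^bits - 1}); 32-bit float pages are multiplied by \code{scale}
#' (the convention used by \code{\link{write_stack}}).
#'
#' @param path Path to a TIFF file.
#' @param pitch_xy_nm,pitch_z_nm Grid metadata in nm (TIFF files rarely carry
#'   trustworthy physical pitch, so the caller supplies it).
#' @param scale Intensity scale for float pages (default
#'   \code{intensity_max()}).
#' @return An \code{\link{image_stack}}.
#' @export
read_stack <- function(path, pitch_xy_nm, pitch_z_nm = pitch_xy_nm,
                       scale = intensity_max()) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel of RGB(A)
    if (!is.null(bits) && bits < 32L) p * (2^bits - 1) else p * scale
  })
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  image_stack(pmax(arr, 0), pitch_xy_nm = pitch_xy_nm, pitch_z_nm = pitch_z_nm)
}

#' Write an image stack as a 32-bit float multi-page TIFF
#'
#' Intensities are stored as \code{value / scale} in single precision, one
#' page per slice. A sidecar text file (\code{<path>.meta.txt}, key=value
#' lines) records the grid metadata and the scale.
#'
#' @param stack An \code{\link{image_stack}} with intensities within
#'   \code{[0, scale]}.
#' @param path Output path.
#' @param scale Intensity scale (default \code{intensity_max()}).
#' @param sidecar Write the metadata sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, scale = intensity_max(), sidecar = TRUE) {
  if (max(stack$data) > scale)
    warnf("intensities above %g are clipped on write", scale)
  pages <- lapply(seq_len(n_slices(stack)),
                  function(i) pmin(get_slice(stack, i) / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  if (sidecar) {
    meta <- c(sprintf("pitch_xy_nm=%.10g", stack$pitch_xy_nm),
              sprintf("pitch_z_nm=%.10g", stack$pitch_z_nm),
              sprintf("n_slices=%d", n_slices(stack)),
              sprintf("intensity_scale=%.10g", scale))
    writeLines(meta, paste0(path, ".meta.txt"))
  }
  invisible(path)
}
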