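#' Threshold from the top fraction of the intensity distribution
#'
#' Chooses the binarization threshold \eqn{\chi} from the probability density
#' of image intensity: the value such that the brightest \code{top_fraction}
#' of the population is retained. By default the population is the pixels
#' with strictly positive intensity — with a mostly dark background an
#' all-pixel percentile would collapse to a near-zero threshold; the
#' structure-weighted population is what makes the rule select the filament
#' outline. Ties at the threshold are retained (the comparison is
#' \code{>=}), so at least \code{ceiling(top_fraction * n)} pixels survive.
#'
#' @param image A numeric matrix (or 3D array, pooled).
#' @param top_fraction Fraction of the population to retain, in (0, 1]
#'   (default 0.15).
#' @param population \code{"positive"} (default) to rank only pixels with
#'   positive intensity, or \code{"all"} to rank every pixel.
#' @return The threshold \eqn{\chi} (a single number).
#' @examples
#' threshold_from_top_fraction(matrix(1:100, 10), 0.15)  # 86
#' @export
threshold_from_top_fraction <- function(image, top_fraction = 0.15,
                                        population = c("positive", "all")) {
  population <- match.arg(population)
  if (length(image) == 0) stopf("empty image")
  if (top_fraction <= 0 || top_fraction > 1) stopf("top_fraction must be in (0, 1]")
  v <- as.numeric(image)
  if (population == "positive") v <- v[v > 0]
  if (length(v) == 0) stopf("empty structure: no positive intensities to threshold")
  k <- ceiling(top_fraction * length(v))
  sort(v, decreasing = TRUE)[k]
}

#' Binarize an image at a threshold
#'
#' The logical-matrix step: 1 where intensity is at or above \eqn{\chi},
#' 0 below. The same operator serves both the outline extraction after
#' scale-band selection (data-derived \eqn{\chi}) and the post-deconvolution
#' binarization (fixed \eqn{\chi = 1}). Re-binarizing a mask with any
#' \eqn{\chi \in (0, 1]} is the identity.
#'
#' @param image A numeric matrix.
#' @param chi Threshold value.
#' @param source_tag Optional label recording which stage produced the mask.
#' @return An object of class \code{binary_mask}: list with \code{data}
#'   (0/1 numeric matrix), \code{threshold_used}, \code{source_tag}.
#' @export
binarize <- function(image, chi, source_tag = NA_character_) {
  stopifnot(is.matrix(image), is.finite(chi))
  m <- (image >= chi) * 1
  structure(list(data = m, threshold_used = chi, source_tag = source_tag),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary mask %d x %d: %d set pixels (%.2f%%), threshold %.6g%s\n",
              nrow(x$data), ncol(x$data), sum(x$data),
              100 * mean(x$data), x$threshold_used,
              if (is.na(x$source_tag)) "" else paste0(" [", x$source_tag, "]")))
  invisible(x)
}

#' Extract masked intensities
#'
#' The final feature-extraction product: the elementwise product of an
#' intensity image with a binary mask. Intensities on the mask support are
#' passed through unchanged; everything else becomes exactly zero. This is
#' extraction, not re-scaling.
#'
#' @param image A numeric matrix (one slice of the expanded stack).
#' @param mask A \code{\link{binarize}} result (or 0/1 matrix) of the same
#'   shape.
#' @return A numeric matrix.
#' @export
apply_mask <- function(image, mask) {
  m <- if (inherits(mask, "binary_mask")) mask$data else mask
  if (!all(dim(image) == dim(m))) stopf("image and mask shapes differ")
  image * m
}
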