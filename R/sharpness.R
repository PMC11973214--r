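#' Entropy focus criterion (EFC) image sharpness
#'
#' Shannon-entropy sharpness of an intensity volume over an optional mask:
#' \deqn{EFC = -\sum_{i=1}^{N} \frac{B_i}{B_{max}}
#'   \ln\!\left[\frac{B_i}{B_{max}}\right], \qquad
#'   B_{max} = \sqrt{\sum_{i=1}^{N} B_i^2},}
#' with \eqn{B_i} the in-mask voxel intensities and \eqn{N} their count.
#' The value is 0 when all image energy sits in a single voxel and maximal
#' for a uniformly gray image, so sharper images score lower. Zero-intensity
#' voxels contribute 0 (the limit \eqn{x \ln x \to 0}). The normalized value
#' divides by the uniform-image entropy \eqn{\sqrt{N}\,\ln(N)/2}, the maximum
#' attainable for \eqn{N} voxels, mapping the criterion onto \[0, 1\].
#'
#' @param image A \linkS4class{ScalarVolume} with non-negative in-mask
#'   intensities, not all zero.
#' @param mask Optional \linkS4class{LabelVolume}; any non-zero label counts
#'   as in-mask. Without a mask all voxels are used.
#' @return An \linkS4class{EFCResult}.
#' @examples
#' a <- array(0, c(4, 4, 4)); a[2, 2, 2] <- 5
#' efc(ScalarVolume(a))  # all energy in one voxel: EFC = 0
#' @export
efc <- function(image, mask = NULL) {
  stopifnot(is(image, "ScalarVolume"))
  b <- image@data
  if (!is.null(mask)) {
    stopifnot(is(mask, "LabelVolume"))
    .stopIfShapeMismatch(image@data, mask@data, "image and mask")
    inMask <- mask@data != 0
    if (!any(inMask)) stop("mask is empty", call. = FALSE)
    b <- b[inMask]
  }
  b <- as.vector(b)
  if (any(b < 0))
    stop("EFC requires non-negative in-mask intensities", call. = FALSE)
  n <- length(b)
  bmax <- sqrt(sum(b^2))
  if (bmax == 0)
    stop("EFC is undefined for an all-zero in-mask image", call. = FALSE)
  p <- b / bmax
  terms <- ifelse(p > 0, -p * log(p), 0)
  raw <- sum(terms)
  maxEntropy <- sqrt(n) * log(n) / 2   # uniform in-mask image
  normalized <- if (maxEntropy > 0) raw / maxEntropy else 0
  normalized <- min(max(normalized, 0), 1)
  new("EFCResult", rawEFC = raw, normalizedEFC = normalized,
      nVoxels = as.integer(n), bMax = bmax)
}
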