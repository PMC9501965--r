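#' Lucy-Richardson deconvolution
#'
#' The multiplicative maximum-likelihood iteration for Poisson-noise
#' imaging: `x_{k+1} = x_k * (psf' (*) (img / (psf (*) x_k)))`, started
#' from `x_0 = img`, where `psf'` is the flipped PSF and `(*)` denotes
#' convolution with reflective (mirror) boundary handling, which avoids
#' edge ringing that would otherwise corrupt tiles. The ratio
#' denominator is guarded by `eps`. Iterates stay nonnegative, total
#' flux of interior-supported signal is conserved, and a delta PSF is a
#' fixed point.
#'
#' @param img nonnegative numeric matrix (or [intensity_image]).
#' @param psf nonnegative kernel with odd sides, normalized to sum 1
#'   (an unnormalized kernel is normalized with a warning; an all-zero
#'   kernel is an error).
#' @param iters iteration count (>= 1).
#' @param eps guard added to the reblurred estimate before division.
#' @return deconvolved numeric matrix (nonnegative, not quantized).
#' @export
richardson_lucy <- function(img, psf, iters = 30L, eps = 1e-12) {
  if (inherits(img, "intensity_image")) img <- img$pixels
  # tolerate FFT round-off from upstream convolutions
  if (min(img) < -1e-6 * max(abs(img), 1)) stop("`img` must be nonnegative")
  img[img < 0] <- 0
  if (any(psf < 0)) stop("`psf` must be nonnegative")
  s <- sum(psf)
  if (s == 0) stop("all-zero PSF")
  if (abs(s - 1) > 1e-8) {
    warning("PSF not normalized; rescaling to sum 1")
    psf <- psf / s
  }
  if (iters < 1) stop("`iters` must be >= 1")
  psf_flip <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf))),
                  drop = FALSE]
  x <- img
  for (k in seq_len(iters)) {
    est <- conv2_reflect(x, psf)
    ratio <- img / (est + eps)
    x <- x * conv2_reflect(ratio, psf_flip)
    x[x < 0] <- 0  # FFT round-off guard
  }
  x
}
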