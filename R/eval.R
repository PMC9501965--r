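#' Construct an intensity line profile
#'
#' A 1D cut through an image: uniformly spaced sample positions in nm
#' with nonnegative intensities, the raw material of FWHM resolution
#' metrology.
#'
#' @param positions strictly increasing, uniformly spaced coordinates
#'   in nm.
#' @param intensities nonnegative values, one per position.
#' @return an object of class `line_profile`.
#' @export
line_profile <- function(positions, intensities) {
  if (length(positions) != length(intensities))
    stop("positions and intensities differ in length")
  if (length(positions) < 3L) stop("a profile needs at least 3 samples")
  dp <- diff(positions)
  if (any(dp <= 0)) stop("positions must be strictly increasing")
  if (max(dp) - min(dp) > 1e-6 * stats::median(dp))
    stop("positions must be uniformly spaced")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities)),
            class = "line_profile")
}

#' Horizontal line profile of an image row
#'
#' @param img an [intensity_image].
#' @param row 1-based row index.
#' @return a [line_profile] with positions at the pixel pitch.
#' @export
profile_row <- function(img, row) {
  stopifnot(inherits(img, "intensity_image"))
  if (row < 1 || row > nrow(img$pixels)) stop("row out of range")
  line_profile((seq_len(ncol(img$pixels)) - 1) * img$pitch_xy,
               img$pixels[row, ])
}

# bilinear sample of a matrix at continuous (row, col) pixel positions;
# coordinates are clamped to the image
bilinear_sample <- function(m, ri, ci) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(ri, 1), H); ci <- pmin(pmax(ci, 1), W)
  r0 <- pmin(floor(ri), H - 1L); c0 <- pmin(floor(ci), W - 1L)
  fr <- ri - r0; fc <- ci - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Line profile along an arbitrary segment
#'
#' Bilinearly interpolated cut between two physical points; used for
#' perpendicular cuts across filaments.
#'
#' @param img an [intensity_image].
#' @param p0,p1 endpoints in nm, `c(first-axis, second-axis)` matching
#'   the matrix (row, column) axes.
#' @param spacing_nm sample spacing (default half a pixel).
#' @return a [line_profile] whose positions start at 0.
#' @export
profile_along <- function(img, p0, p1, spacing_nm = img$pitch_xy / 2) {
  stopifnot(inherits(img, "intensity_image"))
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0) stop("degenerate segment")
  n <- max(3L, floor(len / spacing_nm) + 1L)
  tfrac <- seq(0, 1, length.out = n)
  pts <- cbind(p0[1L] + tfrac * (p1[1L] - p0[1L]),
               p0[2L] + tfrac * (p1[2L] - p0[2L]))
  # nm -> continuous pixel index (pixel i spans [(i-1)*pitch, i*pitch))
  ri <- pts[, 1L] / img$pitch_xy + 0.5
  ci <- pts[, 2L] / img$pitch_xy + 0.5
  line_profile(tfrac * len, bilinear_sample(img$pixels, ri, ci))
}

#' Full width at half maximum of a profile
#'
#' Background (the profile minimum) is subtracted, the half-maximum
#' level located, and the left/right crossings found by linear
#' interpolation between samples; the FWHM is their distance. The
#' profile must have a unique global maximum with a crossing on each
#' side. The width is invariant to uniform intensity scaling and to
#' additive offsets.
#'
#' @param profile a [line_profile].
#' @return width in nm.
#' @export
fwhm <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  p <- profile$positions
  y <- profile$intensities - min(profile$intensities)
  m <- max(y)
  if (m <= 0) stop("flat profile: no peak")
  imax <- which(y == m)
  if (length(imax) > 1L) stop("profile maximum is not unique")
  half <- m / 2
  cross <- function(j1, j2) {
    p[j1] + (half - y[j1]) / (y[j2] - y[j1]) * (p[j2] - p[j1])
  }
  left <- NA_real_
  for (j in seq(imax - 1L, 1L, by = -1L)) {
    if (y[j] < half) { left <- cross(j, j + 1L); break }
  }
  right <- NA_real_
  if (imax < length(y)) {
    for (j in seq(imax + 1L, length(y))) {
      if (y[j] < half) { right <- cross(j - 1L, j); break }
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop("no half-maximum crossing on one side of the peak")
  right - left
}

#' Tile-wise full-image prediction
#'
#' Splits a preprocessed image into model-sized tiles (16 tiles for a
#' 2048-scale frame and a 512 model), runs each through the network,
#' takes the foreground probability and reassembles — the prediction
#' has the input's size and values in `[0, 1]`.
#'
#' @param img an [intensity_image] (8-bit original scale).
#' @param model a trained [anet_model].
#' @return numeric matrix of foreground probabilities.
#' @export
predict_full <- function(img, model) {
  stopifnot(inherits(img, "intensity_image"))
  side <- model$config$input_side
  d <- dim(img$pixels)
  if (any(d %% side != 0))
    stop("image sides must be multiples of the model input side ", side)
  grid <- tile(img, side)
  out <- matrix(0, d[1L], d[2L])
  k <- 1L
  for (i in seq_len(grid$rows)) {
    for (j in seq_len(grid$cols)) {
      pr <- anet_predict(model, grid$tiles[[k]])
      out[((i - 1L) * side + 1L):(i * side),
          ((j - 1L) * side + 1L):(j * side)] <- pr
      k <- k + 1L
    }
  }
  out
}

#' Binarize a probability map
#'
#' @param prediction numeric matrix in `[0, 1]`.
#' @param threshold foreground cut (default 0.5).
#' @return 0/1 matrix.
#' @export
binarize_mask <- function(prediction, threshold = 0.5) {
  if (any(prediction < 0) || any(prediction > 1))
    stop("`prediction` must lie in [0, 1]")
  (prediction >= threshold) + 0
}

#' Multiply a binary mask into a test image
#'
#' The shrinkage outline selects pixels: intensities inside the mask
#' are preserved exactly, everything outside becomes zero, so no pixel
#' value ever increases.
#'
#' @param test_img an [intensity_image].
#' @param mask 0/1 matrix (or binary [intensity_image]) of equal shape.
#' @return an [intensity_image].
#' @export
apply_mask <- function(test_img, mask) {
  stopifnot(inherits(test_img, "intensity_image"))
  if (inherits(mask, "intensity_image")) mask <- mask$pixels
  if (!identical(dim(mask), dim(test_img$pixels)))
    stop("shape mismatch between image and mask")
  if (!all(mask %in% c(0, 1))) stop("`mask` must be binary")
  intensity_image(test_img$pixels * mask, bit_depth = test_img$bit_depth,
                  pitch_xy = test_img$pitch_xy)
}

#' SSIM and PSNR between two images
#'
#' Standard SSIM (Gaussian window of side 11, sigma 1.5, K1 = 0.01,
#' K2 = 0.03) averaged over the frame, and PSNR, both on the images'
#' shared bit-depth dynamic range. Identical images give SSIM 1 and
#' infinite PSNR, reported as the capped sentinel 100 dB. These
#' fidelity metrics are reported for completeness; they are known to be
#' uninformative for structure-extraction output.
#'
#' @param result,reference [intensity_image]s of equal shape and bit
#'   depth.
#' @return named numeric vector `c(ssim = , psnr = )`.
#' @export
image_metrics <- function(result, reference) {
  stopifnot(inherits(result, "intensity_image"),
            inherits(reference, "intensity_image"))
  if (!identical(dim(result$pixels), dim(reference$pixels)))
    stop("shape mismatch")
  if (result$bit_depth != reference$bit_depth)
    stop("bit depths differ")
  L <- 2^result$bit_depth - 1
  x <- result$pixels; y <- reference$pixels
  ax <- (-5):5
  w1 <- exp(-ax^2 / (2 * 1.5^2))
  w <- outer(w1, w1); w <- w / sum(w)
  mu_x <- conv2_reflect(x, w); mu_y <- conv2_reflect(y, w)
  sxx <- conv2_reflect(x * x, w) - mu_x^2
  syy <- conv2_reflect(y * y, w) - mu_y^2
  sxy <- conv2_reflect(x * y, w) - mu_x * mu_y
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ssim_map <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mse <- mean((x - y)^2)
  psnr <- if (mse == 0) 100 else 10 * log10(L^2 / mse)
  c(ssim = mean(ssim_map), psnr = psnr)
}

#' Assemble result slices into a 3D stack
#'
#' Layer-by-layer 3D reconstruction: registered equal-size slices are
#' ordered along z with an explicit z pitch.
#'
#' @param slices list of [intensity_image]s (equal shape/bit depth).
#' @param pitch_z z interval in nm.
#' @return an [image_stack].
#' @export
stack_3d <- function(slices, pitch_z) {
  image_stack(slices, pitch_z = pitch_z)
}

#' Maximum-intensity projection of a stack
#'
#' @param stack an [image_stack].
#' @return an [intensity_image] of the per-pixel maxima over z.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  out <- Reduce(pmax, lapply(stack$slices, function(s) s$pixels))
  intensity_image(out, bit_depth = stack$slices[[1L]]$bit_depth,
                  pitch_xy = stack$slices[[1L]]$pitch_xy)
}
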