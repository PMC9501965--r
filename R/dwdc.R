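#' DWDC label-generation configuration
#'
#' Parameters of the classical label generator: discrete-wavelet
#' denoising followed by Lucy-Richardson deconvolution and a final
#' binarization. Defaults: sym4 wavelet, 3 levels, BayesShrink soft
#' thresholding, 30 deconvolution iterations, Otsu binarization cut.
#'
#' @param wavelet wavelet family name.
#' @param levels decomposition depth (>= 1).
#' @param shrink_rule `"bayes"` or `"none"`.
#' @param rl_iters Lucy-Richardson iteration count (>= 1).
#' @param binarize_threshold final cut on the deconvolved intensity, or
#'   `NULL` for Otsu.
#' @return a list of class `dwdc_config`.
#' @export
dwdc_config <- function(wavelet = "sym4", levels = 3L,
                        shrink_rule = "bayes", rl_iters = 30L,
                        binarize_threshold = NULL) {
  if (levels < 1L) stop("`levels` must be >= 1")
  if (rl_iters < 1L) stop("`rl_iters` must be >= 1")
  structure(list(wavelet = wavelet, levels = levels,
                 shrink_rule = shrink_rule, rl_iters = rl_iters,
                 binarize_threshold = binarize_threshold),
            class = "dwdc_config")
}

#' Generate a binary high-resolution label image
#'
#' The DWDC pipeline: wavelet shrinkage denoising, Lucy-Richardson
#' deconvolution with the Gaussian PSF implied by the optical model
#' sampled at the image's own pitch, and hard binarization. The output
#' is a 0/1 [intensity_image] registered with the input; an all-zero
#' input maps to an all-zero label, and the label is idempotent under
#' re-binarization.
#'
#' @param img an [intensity_image] (typically the interpolated
#'   original).
#' @param optical an [optical_model].
#' @param cfg a [dwdc_config].
#' @return a binary (values 0/1, 8-bit) [intensity_image].
#' @export
make_label <- function(img, optical = optical_model(),
                       cfg = dwdc_config()) {
  stopifnot(inherits(img, "intensity_image"))
  den <- dwt_denoise(img, wavelet = cfg$wavelet, levels = cfg$levels,
                     shrink_rule = cfg$shrink_rule)
  psf <- gaussian_psf(optical, pitch_nm = img$pitch_xy)
  dec <- richardson_lucy(den$pixels, psf, iters = cfg$rl_iters)
  if (max(dec) == 0) {
    lab <- matrix(0, nrow(dec), ncol(dec))
  } else {
    t <- if (is.null(cfg$binarize_threshold)) otsu_threshold(dec)
         else cfg$binarize_threshold
    lab <- (dec >= t) + 0
  }
  intensity_image(lab, bit_depth = 8L, pitch_xy = img$pitch_xy)
}

#' Pair originals with labels into a tiled training dataset
#'
#' Mirrors the dataset construction used for training: each original is
#' converted to 8-bit, both members are tiled to `tile_side`, and tiles
#' are paired index-wise. A 2048-scale pair at side 512 yields 16 tile
#' pairs. When `dir` is given, tile TIFFs and a CSV manifest (one row
#' per tile pair, same tile index in both columns) are written.
#'
#' @param originals list of 16-bit (or 8-bit) [intensity_image]s.
#' @param labels list of binary [intensity_image]s with matching
#'   geometry.
#' @param tile_side tile side in px.
#' @param dir optional output directory.
#' @return list with `pairs` (each `list(x = 8-bit tile, g = 0/1 label
#'   matrix)`) and `manifest`.
#' @export
pair_dataset <- function(originals, labels, tile_side = 512,
                         dir = NULL) {
  if (length(originals) != length(labels))
    stop("original and label counts differ")
  pairs <- list()
  rows <- list()
  for (i in seq_along(originals)) {
    o <- originals[[i]]; l <- labels[[i]]
    if (!identical(dim(o$pixels), dim(l$pixels)))
      stop("size mismatch between original and label ", i)
    o8 <- if (o$bit_depth == 16L) convert_16_to_8(o) else o
    to <- tile(o8, tile_side)
    tl <- tile(l, tile_side)
    for (k in seq_along(to$tiles)) {
      pairs[[length(pairs) + 1L]] <-
        list(x = to$tiles[[k]], g = (tl$tiles[[k]]$pixels > 0) + 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, tile = k,
        orig_tile = sprintf("orig_%03d_%02d.tif", i, k),
        label_tile = sprintf("label_%03d_%02d.tif", i, k),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
    else data.frame(image = integer(), tile = integer(),
                    orig_tile = character(), label_tile = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(dir) && length(pairs)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_len(nrow(manifest))) {
      p <- pairs[[r]]
      write_tiff(p$x, file.path(dir, manifest$orig_tile[r]))
      write_tiff(intensity_image(p$g * 255, bit_depth = 8L,
                                 pitch_xy = p$x$pitch_xy),
                 file.path(dir, manifest$label_tile[r]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(pairs = pairs, manifest = manifest)
}
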