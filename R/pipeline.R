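# Scaled end-to-end study: phantom dataset -> DWDC labels -> A-net
# training -> masked prediction -> IoU and FWHM metrology against the
# known ground truth.

#' Perpendicular-cut FWHM measurements across filaments
#'
#' Places cuts perpendicular to the true filament centerlines of a
#' scene and measures the FWHM of the image intensity along each cut.
#' Cut centres are sampled at interior arc fractions of each curve and
#' kept only when isolated (no other filament within `min_sep_nm`), so
#' each profile has a single peak attributable to one filament; cuts
#' whose profile has no unique peak or no half-max crossing are
#' dropped.
#'
#' @param img an [intensity_image] registered with the scene.
#' @param scene the [filament_scene] ground truth.
#' @param cuts_per_curve number of candidate cut centres per filament.
#' @param half_len_nm half-length of each cut.
#' @param spacing_nm profile sample spacing.
#' @param min_sep_nm minimum distance to any other filament.
#' @return numeric vector of FWHM values in nm (possibly empty), with
#'   attribute `centers` (matrix of the cut centres used).
#' @export
fwhm_perpendicular_cuts <- function(img, scene, cuts_per_curve = 5,
                                    half_len_nm = 1250,
                                    spacing_nm = img$pitch_xy / 2,
                                    min_sep_nm = 1500) {
  stopifnot(inherits(img, "intensity_image"),
            inherits(scene, "filament_scene"))
  all_pts <- lapply(scene$curves, resample_polyline,
                    step = scene$field_nm / 200)
  widths <- numeric(0)
  centers <- NULL
  for (ci in seq_along(scene$curves)) {
    cv <- scene$curves[[ci]]
    pts <- resample_polyline(cv, curve_length_nm(cv) /
                               max(20, cuts_per_curve * 4))
    n <- nrow(pts)
    if (n < 5L) next
    at <- unique(pmax(3L, pmin(n - 2L,
                               round(seq(0.2, 0.8,
                                         length.out = cuts_per_curve) * n))))
    others <- do.call(rbind, all_pts[-ci])
    for (i in at) {
      p <- pts[i, ]
      if (!is.null(others)) {
        d2 <- min((others[, 1L] - p[1L])^2 + (others[, 2L] - p[2L])^2)
        if (d2 < min_sep_nm^2) next
      }
      tang <- pts[i + 1L, ] - pts[i - 1L, ]
      tang <- tang / sqrt(sum(tang^2))
      nrm <- c(-tang[2L], tang[1L])
      p0 <- p - half_len_nm * nrm
      p1 <- p + half_len_nm * nrm
      w <- tryCatch(fwhm(profile_along(img, p0, p1, spacing_nm)),
                    error = function(e) NA_real_)
      if (is.finite(w)) {
        widths <- c(widths, w)
        centers <- rbind(centers, p)
      }
    }
  }
  attr(widths, "centers") <- centers
  widths
}

# intersection-over-union of two binary masks
mask_iou <- function(a, b) {
  inter <- sum(a > 0 & b > 0)
  uni <- sum(a > 0 | b > 0)
  if (uni == 0) return(NA_real_)
  inter / uni
}

#' Run the scaled phantom study end to end
#'
#' Generates a paired phantom dataset, builds DWDC labels from the
#' degraded observations (threshold denoising, wavelet shrinkage,
#' Lucy-Richardson deconvolution, binarization), trains an A-net on the
#' (8-bit observation, label) pairs, and evaluates on the held-out test
#' pairs: foreground IoU of the binarized prediction against the
#' phantom truth, and perpendicular-cut FWHM of the degraded inputs
#' versus the masked results. The default scale (40/10 pairs of
#' 64 x 64 px, depth-2 network, 30 epochs) runs on a single CPU in a
#' few minutes; every stage is driven by `seed`.
#'
#' @param n_train,n_test pair counts.
#' @param config a [phantom_config] (the study conditions).
#' @param net an [anet_config] sized to the observations.
#' @param dwdc a [dwdc_config] for label generation.
#' @param epochs,lr training schedule.
#' @param mask_threshold binarization cut on foreground probability.
#' @param seed master seed for dataset, labels and training.
#' @param verbose print training progress.
#' @return list with per-image IoU, mean IoU, FWHM vectors for degraded
#'   and result images, their means and ratio, the trained model, and
#'   the dataset.
#' @export
run_phantom_experiment <- function(n_train = 40, n_test = 10,
                                   config = phantom_config(),
                                   net = anet_config(
                                     input_side = config$image_px,
                                     depth = 2, base_channels = 8),
                                   dwdc = dwdc_config(),
                                   epochs = 30, lr = 3e-3,
                                   mask_threshold = 0.5,
                                   seed = 1, verbose = FALSE) {
  ds <- make_dataset(n_train, n_test, config = config, seed = seed)
  make_training_pair <- function(pair) {
    den <- threshold_denoise(pair$observed)
    lab <- make_label(den, config$optical, dwdc)
    list(x = convert_16_to_8(pair$observed, minmax = TRUE),
         g = lab$pixels)
  }
  train_pairs <- lapply(ds$train, make_training_pair)
  model <- anet_train(train_pairs, net,
                      train_config(epochs = epochs, batch = 1, lr = lr,
                                   seed = seed + 1L),
                      verbose = verbose)
  iou <- numeric(length(ds$test))
  fwhm_in <- numeric(0); fwhm_out <- numeric(0)
  results <- vector("list", length(ds$test))
  for (i in seq_along(ds$test)) {
    pair <- ds$test[[i]]
    prob <- anet_predict(model, convert_16_to_8(pair$observed,
                                                minmax = TRUE))
    mask <- binarize_mask(prob, mask_threshold)
    result <- apply_mask(pair$observed, mask)
    results[[i]] <- result
    iou[i] <- mask_iou(mask, pair$truth_mask_obs)
    w_in <- fwhm_perpendicular_cuts(pair$observed, pair$scene)
    w_out <- fwhm_perpendicular_cuts(result, pair$scene)
    fwhm_in <- c(fwhm_in, w_in)
    fwhm_out <- c(fwhm_out, w_out)
  }
  list(iou = iou, mean_iou = mean(iou, na.rm = TRUE),
       fwhm_degraded = fwhm_in, fwhm_result = fwhm_out,
       mean_fwhm_degraded = mean(fwhm_in),
       mean_fwhm_result = mean(fwhm_out),
       fwhm_ratio = mean(fwhm_in) / mean(fwhm_out),
       n_cuts_degraded = length(fwhm_in),
       n_cuts_result = length(fwhm_out),
       model = model, dataset = ds, results = results)
}
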