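#' Noise model of the detector
#'
#' Shot noise is Poisson on the expected count; read noise is additive
#' Gaussian; `offset` is a constant background level added before the
#' shot noise (it is itself Poisson-distributed when `poisson = TRUE`,
#' as background photons are).
#'
#' @param gaussian_sigma read-noise standard deviation in counts.
#' @param poisson logical, apply Poisson shot noise.
#' @param offset background level in counts.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 10, poisson = TRUE, offset = 100) {
  if (gaussian_sigma < 0) stop("`gaussian_sigma` must be >= 0")
  if (offset < 0) stop("`offset` must be >= 0")
  structure(list(gaussian_sigma = gaussian_sigma, poisson = isTRUE(poisson),
                 offset = offset), class = "noise_model")
}

# run `expr` under a seed without disturbing the caller's RNG stream;
# seed = NULL uses (and advances) the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random filament scene
#'
#' Ground-truth scenes are sparse, smoothly curved filaments: each curve
#' is a constant-speed planar walk whose heading receives small Gaussian
#' increments, giving fibre-like tracks of bounded curvature. Scenes are
#' fully reproducible from their seed.
#'
#' @param n_filaments number of filaments (>= 0).
#' @param field_nm side of the square physical field in nm.
#' @param seed RNG seed; `NULL` uses the current RNG stream.
#' @param width_nm rendered filament width in nm (default 50 nm:
#'   above the ~24 nm physical microtubule, well below the PSF).
#' @param amplitude peak emission intensity per curve, in expected
#'   counts per pitch-length of filament.
#' @param step_nm arc-length step of the generating walk.
#' @param turn_sd heading increment SD per step, radians.
#' @return an object of class `filament_scene` with a list of curves
#'   (n x 2 matrices of xy control points in nm).
#' @export
generate_scene <- function(n_filaments, field_nm = 16000, seed = NULL,
                           width_nm = 50, amplitude = 2000,
                           step_nm = field_nm / 100, turn_sd = 0.08) {
  if (field_nm <= 0) stop("`field_nm` must be positive")
  if (n_filaments < 0) stop("`n_filaments` must be >= 0")
  if (width_nm <= 0 || amplitude <= 0)
    stop("`width_nm` and `amplitude` must be positive")
  curves <- with_seed(seed, {
    lapply(seq_len(n_filaments), function(i) {
      # start inside the central 80% so curves have room to develop
      p <- stats::runif(2, 0.1 * field_nm, 0.9 * field_nm)
      theta <- stats::runif(1, 0, 2 * pi)
      max_steps <- ceiling(2.5 * field_nm / step_nm)
      pts <- matrix(NA_real_, max_steps + 1L, 2L)
      pts[1L, ] <- p
      n_pts <- 1L
      for (s in seq_len(max_steps)) {
        theta <- theta + stats::rnorm(1, 0, turn_sd)
        p <- p + step_nm * c(cos(theta), sin(theta))
        if (any(p < 0) || any(p > field_nm)) break
        n_pts <- n_pts + 1L
        pts[n_pts, ] <- p
      }
      pts[seq_len(n_pts), , drop = FALSE]
    })
  })
  # drop degenerate single-point curves (immediate wall hit)
  curves <- Filter(function(cv) nrow(cv) >= 2L, curves)
  structure(list(curves = curves, width_nm = width_nm,
                 amplitude = amplitude, field_nm = field_nm, seed = seed),
            class = "filament_scene")
}

#' @export
print.filament_scene <- function(x, ...) {
  cat(sprintf("<filament_scene> %d curves in a %g x %g nm field\n",
              length(x$curves), x$field_nm, x$field_nm))
  invisible(x)
}

# resample a polyline at a fixed arc step; returns an n x 2 matrix
resample_polyline <- function(pts, step) {
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  if (total <= 0) return(pts[1L, , drop = FALSE])
  s <- seq(0, total, by = step)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i >= length(cum)] <- length(cum) - 1L
  frac <- (s - cum[i]) / pmax(len[i], .Machine$double.eps)
  pts[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac
}

curve_length_nm <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

#' Rasterize the ground truth of a scene
#'
#' Renders the scene on a supersampled grid: each arc-length element
#' `ds` of a curve deposits `amplitude * ds / pitch` counts into its
#' nearest pixel, so the integrated intensity equals
#' `amplitude * length / pitch` and a straight axis-aligned filament has
#' a per-pixel value of `amplitude`. The centerline mask marks every
#' pixel any curve passes through. When `width_nm` exceeds the pitch the
#' intensity (not the mask) is spread with a FWHM-matched Gaussian.
#'
#' @param scene a [filament_scene].
#' @param supersample_pitch_nm grid pitch in nm; must be <= 63 nm so the
#'   truth is sampled at least as finely as interpolated confocal data.
#' @return list with `intensity` (numeric matrix, counts), `mask`
#'   (0/1 integer matrix of centerline pixels), and `pitch_nm`.
#' @export
render_truth <- function(scene, supersample_pitch_nm = 62.5) {
  stopifnot(inherits(scene, "filament_scene"))
  if (supersample_pitch_nm > 63)
    stop("`supersample_pitch_nm` must be <= 63 nm")
  pitch <- supersample_pitch_nm
  n <- round(scene$field_nm / pitch)
  img <- matrix(0, n, n)
  mask <- matrix(0L, n, n)
  step <- pitch / 4            # fine arc step for the Riemann deposit
  for (cv in scene$curves) {
    pts <- resample_polyline(cv, step)
    # nm -> pixel index; pixel i covers [(i-1)*pitch, i*pitch)
    ij <- floor(pts / pitch) + 1L
    keep <- ij[, 1L] >= 1L & ij[, 1L] <= n & ij[, 2L] >= 1L & ij[, 2L] <= n
    ij <- ij[keep, , drop = FALSE]
    if (!nrow(ij)) next
    lin <- (ij[, 2L] - 1L) * n + ij[, 1L]
    dep <- scene$amplitude * step / pitch
    add <- tapply(rep(dep, length(lin)), lin, sum)
    idx <- as.integer(names(add))
    img[idx] <- img[idx] + as.numeric(add)
    mask[lin] <- 1L
  }
  if (scene$width_nm > pitch) {
    taps <- gaussian_taps(scene$width_nm / FWHM_SIGMA, pitch)
    k <- outer(taps, taps); k <- k / sum(k)
    img <- conv2_same(img, k)
  }
  list(intensity = img, mask = mask, pitch_nm = pitch)
}

# sum-bin a matrix by an integer factor
bin_sum <- function(x, f) {
  n1 <- nrow(x) %/% f; n2 <- ncol(x) %/% f
  x <- x[seq_len(n1 * f), seq_len(n2 * f), drop = FALSE]
  # sum over f x f blocks via two reshapes
  x <- rowsum(x, rep(seq_len(n1), each = f))
  t(rowsum(t(x), rep(seq_len(n2), each = f)))
}

#' Degrade a ground-truth image through the observation model
#'
#' Implements the forward model `L = H * f + N`: the truth `H` is
#' convolved with the Gaussian PSF `f` (sigma = `r_perp`, FWHM
#' 2.355 `r_perp`, about 657 nm by default), sum-binned down to the
#' confocal pitch, offset by the background, corrupted by Poisson shot
#' noise and Gaussian read noise, and quantized to 16 bits with
#' clipping.
#'
#' @param truth result of [render_truth()] (or a list with `intensity`
#'   and `pitch_nm`).
#' @param optical an [optical_model].
#' @param noise a [noise_model].
#' @param out_pitch_nm output pixel pitch; must be an integer multiple
#'   of the truth pitch.
#' @param seed RNG seed for the noise draw; `NULL` uses the current
#'   stream.
#' @return a 16-bit [intensity_image] at `out_pitch_nm`.
#' @export
degrade <- function(truth, optical = optical_model(),
                    noise = noise_model(), out_pitch_nm = 250,
                    seed = NULL) {
  f <- out_pitch_nm / truth$pitch_nm
  if (abs(f - round(f)) > 1e-9)
    stop("`out_pitch_nm` must be an integer multiple of the truth pitch")
  f <- as.integer(round(f))
  psf <- gaussian_psf(optical, pitch_nm = truth$pitch_nm)
  if (nrow(psf) > nrow(truth$intensity) || ncol(psf) > ncol(truth$intensity))
    stop("PSF support (", nrow(psf), " px) is wider than the field")
  blurred <- conv2_same(truth$intensity, psf)
  blurred[blurred < 0] <- 0   # FFT round-off can dip below zero
  coarse <- if (f > 1L) bin_sum(blurred, f) else blurred
  expected <- coarse + noise$offset
  observed <- with_seed(seed, {
    v <- if (noise$poisson) {
      stats::rpois(length(expected), lambda = expected)
    } else expected
    if (noise$gaussian_sigma > 0)
      v <- v + stats::rnorm(length(expected), 0, noise$gaussian_sigma)
    v
  })
  q <- floor(pmin(pmax(observed, 0), 65535) + 0.5)
  intensity_image(matrix(q, nrow(coarse), ncol(coarse)),
                  bit_depth = 16L, pitch_xy = out_pitch_nm)
}

#' Configuration of the phantom dataset generator
#'
#' The defaults describe the study conditions the package is exercised
#' under: a 16 micron field observed at 250 nm pitch (64 x 64 px),
#' truth supersampled 4x (62.5 nm), 2-6 filaments per scene, 50 nm
#' filament width, peak amplitude 2000 counts, background 100 counts,
#' read noise 10 counts with Poisson shot noise on.
#'
#' @param image_px observed image side in px.
#' @param out_pitch_nm observed pixel pitch in nm.
#' @param supersample integer supersampling factor of the truth grid.
#' @param n_filaments_range inclusive integer range for filaments per scene.
#' @param width_nm,amplitude passed to [generate_scene()].
#' @param optical an [optical_model].
#' @param noise a [noise_model].
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(image_px = 64, out_pitch_nm = 250,
                           supersample = 4,
                           n_filaments_range = c(2, 6),
                           width_nm = 50, amplitude = 2000,
                           optical = optical_model(),
                           noise = noise_model()) {
  structure(list(image_px = image_px, out_pitch_nm = out_pitch_nm,
                 supersample = supersample,
                 n_filaments_range = n_filaments_range,
                 width_nm = width_nm, amplitude = amplitude,
                 optical = optical, noise = noise),
            class = "phantom_config")
}

# one phantom pair from one sub-seed
make_pair <- function(cfg, seed) {
  n_f <- with_seed(seed, {
    sample(cfg$n_filaments_range[1L]:cfg$n_filaments_range[2L], 1L)
  })
  field <- cfg$image_px * cfg$out_pitch_nm
  scene <- generate_scene(n_f, field_nm = field, seed = seed + 1L,
                          width_nm = cfg$width_nm,
                          amplitude = cfg$amplitude)
  truth <- render_truth(scene, cfg$out_pitch_nm / cfg$supersample)
  observed <- degrade(truth, cfg$optical, cfg$noise,
                      out_pitch_nm = cfg$out_pitch_nm, seed = seed + 2L)
  # truth foreground at the observed pitch: any supersampled centerline
  # pixel inside an observed pixel marks it as filament
  mask_obs <- (bin_sum(truth$mask + 0, cfg$supersample) > 0) + 0L
  list(scene = scene, truth = truth, observed = observed,
       truth_mask_obs = mask_obs)
}

#' Generate a paired phantom dataset
#'
#' Produces `n_train + n_test` independent phantom pairs (degraded
#' observation + registered ground truth). A single seed drives the
#' whole dataset; per-image sub-seeds are drawn from it by counter, so
#' pairs are independent yet the dataset is byte-reproducible. When
#' `dir` is given, observed and truth-mask TIFFs plus a CSV manifest are
#' written there.
#'
#' @param n_train,n_test pair counts (>= 1); the reference composition
#'   is 200/50, the package's scaled default study uses 40/10.
#' @param config a [phantom_config].
#' @param seed integer seed for the dataset.
#' @param dir optional output directory for TIFFs and manifest.
#' @param force overwrite an existing non-empty `dir`.
#' @return list with `train` and `test` lists of pairs, and `manifest`
#'   data frame.
#' @export
make_dataset <- function(n_train, n_test, config = phantom_config(),
                         seed = 1, dir = NULL, force = FALSE) {
  if (n_train < 1 || n_test < 1) stop("pair counts must be >= 1")
  n <- n_train + n_test
  # counter-derived sub-seeds, kept well inside 32-bit range
  sub <- (as.integer(seed) %% 100000L) * 10000L + 3L * seq_len(n)
  pairs <- lapply(sub, function(s) make_pair(config, s))
  split <- list(train = pairs[seq_len(n_train)],
                test = pairs[n_train + seq_len(n_test)])
  manifest <- data.frame(
    index = seq_len(n),
    role = rep(c("train", "test"), c(n_train, n_test)),
    n_filaments = vapply(pairs, function(p) length(p$scene$curves),
                         integer(1)),
    observed = sprintf("observed_%03d.tif", seq_len(n)),
    truth_mask = sprintf("truth_mask_%03d.tif", seq_len(n)),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !force)
      stop("output dir exists and is not empty; use force = TRUE")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n)) {
      write_tiff(pairs[[i]]$observed, file.path(dir, manifest$observed[i]))
      mask8 <- intensity_image(pairs[[i]]$truth_mask_obs * 255,
                               bit_depth = 8L,
                               pitch_xy = config$out_pitch_nm)
      write_tiff(mask8, file.path(dir, manifest$truth_mask[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  c(split, list(manifest = manifest, config = config, seed = seed))
}
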