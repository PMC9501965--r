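# Periodized orthogonal discrete wavelet transform. Filters are the
# standard Daubechies/symlet coefficients; the high-pass is the
# quadrature mirror g[k] = (-1)^(k+1) h[L-1-k], reconstruction filters
# are the time-reversed decomposition filters. The analysis/synthesis
# phase is L/2, which makes the transform orthonormal on even-length
# signals and gives machine-precision reconstruction.

wavelet_filters <- function(name) {
  dec_lo <- switch(name,
    haar = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(0.48296291314469025, 0.836516303737469,
            0.22414386804185735, -0.12940952255092145),
    sym4 = c(-0.07576571478927333, -0.02963552764599851,
             0.49761866763201545, 0.8037387518059161,
             0.29785779560527736, -0.09921954357684722,
             -0.012603967262037833, 0.0322231006040427),
    stop("unknown wavelet: ", name)
  )
  L <- length(dec_lo)
  k <- seq_len(L) - 1L
  dec_hi <- (-1)^(k + 1) * rev(dec_lo)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rev(dec_lo), rec_hi = rev(dec_hi), length = L)
}

# one analysis level along a vector (periodic boundary)
dwt1 <- function(x, flt) {
  N <- length(x)
  if (N %% 2L) stop("signal length must be even at every level")
  L <- flt$length; s <- L %/% 2L
  half <- N %/% 2L
  cA <- numeric(half); cD <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (k in 0:(L - 1L)) {
    idx <- ((base + s - k) %% N) + 1L
    cA <- cA + flt$dec_lo[k + 1L] * x[idx]
    cD <- cD + flt$dec_hi[k + 1L] * x[idx]
  }
  list(cA = cA, cD = cD)
}

idwt1 <- function(cA, cD, flt) {
  half <- length(cA); N <- 2L * half
  L <- flt$length; s <- L %/% 2L
  u <- numeric(N); v <- numeric(N)
  u[seq(2L, N, 2L)] <- cA
  v[seq(2L, N, 2L)] <- cD
  x <- numeric(N)
  base <- seq_len(N) - 1L
  for (k in 0:(L - 1L)) {
    idx <- ((base - k + s) %% N) + 1L
    x <- x + flt$rec_lo[k + 1L] * u[idx] + flt$rec_hi[k + 1L] * v[idx]
  }
  x
}

# single-level 2D transform: columns first, then rows of each half
dwt2_level <- function(x, flt) {
  lo <- apply(x, 2L, function(col) dwt1(col, flt)$cA)
  hi <- apply(x, 2L, function(col) dwt1(col, flt)$cD)
  split_rows <- function(m) {
    a <- t(apply(m, 1L, function(row) dwt1(row, flt)$cA))
    d <- t(apply(m, 1L, function(row) dwt1(row, flt)$cD))
    list(a = a, d = d)
  }
  l <- split_rows(lo); h <- split_rows(hi)
  # cH: detail along rows (horizontal features), cV: detail along cols
  list(cA = l$a, cH = h$a, cV = l$d, cD = h$d)
}

idwt2_level <- function(cf, flt) {
  join_rows <- function(a, d) {
    t(vapply(seq_len(nrow(a)),
             function(i) idwt1(a[i, ], d[i, ], flt),
             numeric(2L * ncol(a))))
  }
  lo <- join_rows(cf$cA, cf$cV)
  hi <- join_rows(cf$cH, cf$cD)
  vapply(seq_len(ncol(lo)),
         function(j) idwt1(lo[, j], hi[, j], flt),
         numeric(2L * nrow(lo)))
}

#' Multilevel 2D discrete wavelet transform
#'
#' Periodized orthonormal DWT of a matrix. `dwt2(x)` returns the
#' approximation at the coarsest level plus a list of detail triplets
#' (`cH`, `cV`, `cD`) per level; `idwt2` inverts it to machine
#' precision.
#'
#' @param x numeric matrix; both sides must be divisible by `2^levels`.
#' @param wavelet one of `"haar"`, `"db2"`, `"sym4"`.
#' @param levels decomposition depth (>= 1).
#' @return for `dwt2`, a list with `cA` and `details`; `idwt2` returns
#'   the reconstructed matrix.
#' @export
dwt2 <- function(x, wavelet = "sym4", levels = 1L) {
  if (levels < 1L) stop("`levels` must be >= 1")
  if (any(dim(x) %% 2L^levels != 0L))
    stop("matrix sides must be divisible by 2^levels")
  flt <- wavelet_filters(wavelet)
  details <- vector("list", levels)
  cA <- x
  for (l in seq_len(levels)) {
    cf <- dwt2_level(cA, flt)
    details[[l]] <- cf[c("cH", "cV", "cD")]
    cA <- cf$cA
  }
  list(cA = cA, details = details, wavelet = wavelet, levels = levels)
}

#' @rdname dwt2
#' @param decomp result of [dwt2()].
#' @export
idwt2 <- function(decomp) {
  flt <- wavelet_filters(decomp$wavelet)
  cA <- decomp$cA
  for (l in rev(seq_len(decomp$levels))) {
    cf <- decomp$details[[l]]
    cA <- idwt2_level(list(cA = cA, cH = cf$cH, cV = cf$cV, cD = cf$cD),
                      flt)
  }
  cA
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# BayesShrink subband threshold: sigma^2 / sigma_x with the signal SD
# estimated from the subband after removing the noise variance
bayes_threshold <- function(band, sigma_noise) {
  var_band <- mean(band^2)
  sigma_x <- sqrt(max(var_band - sigma_noise^2, 0))
  if (sigma_x == 0) return(max(abs(band)))  # pure noise: kill the band
  sigma_noise^2 / sigma_x
}

#' Wavelet shrinkage denoising
#'
#' Multilevel 2D DWT, shrinkage of the detail coefficients, inverse
#' transform, and clipping back to the valid intensity range. The
#' default rule is BayesShrink soft-thresholding with the noise SD
#' estimated from the finest diagonal band by the robust median rule
#' `sigma = median(|cD1|) / 0.6745`. `shrink_rule = "none"` (or a fixed
#' `threshold` of 0) reproduces the input up to quantization.
#'
#' @param img an [intensity_image].
#' @param wavelet wavelet family name (`"haar"`, `"db2"`, `"sym4"`).
#' @param levels decomposition depth.
#' @param shrink_rule `"bayes"` or `"none"`.
#' @param threshold optional fixed soft threshold overriding the rule.
#' @return a denoised [intensity_image].
#' @export
dwt_denoise <- function(img, wavelet = "sym4", levels = 3L,
                        shrink_rule = c("bayes", "none"),
                        threshold = NULL) {
  stopifnot(inherits(img, "intensity_image"))
  shrink_rule <- match.arg(shrink_rule)
  if (any(dim(img$pixels) < 2L^levels))
    stop("image sides must be at least 2^levels")
  dec <- dwt2(img$pixels, wavelet = wavelet, levels = levels)
  sigma_noise <- stats::median(abs(dec$details[[1L]]$cD)) / 0.6745
  for (l in seq_len(levels)) {
    for (b in c("cH", "cV", "cD")) {
      band <- dec$details[[l]][[b]]
      t <- if (!is.null(threshold)) threshold
           else if (shrink_rule == "none") 0
           else bayes_threshold(band, sigma_noise)
      dec$details[[l]][[b]] <- soft_threshold(band, t)
    }
  }
  rec <- idwt2(dec)
  rng <- 2^img$bit_depth - 1
  rec <- floor(pmin(pmax(rec, 0), rng) + 0.5)
  intensity_image(rec, bit_depth = img$bit_depth, pitch_xy = img$pitch_xy)
}
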