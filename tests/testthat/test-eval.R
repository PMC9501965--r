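test_that("FWHM of a sampled Gaussian matches the closed form", {
  pr <- gaussian_profile(sigma_nm = 100, spacing_nm = 10)
  expect_equal(fwhm(pr), 2 * sqrt(2 * log(2)) * 100, tolerance = 1 / 235)
})

test_that("interpolated crossings give 200 nm for the 5-point triangle", {
  pr <- line_profile((0:4) * 100, c(0, 0.5, 1, 0.5, 0))
  expect_equal(fwhm(pr), 200, tolerance = 1e-12)
})

test_that("degenerate profiles are rejected", {
  expect_error(fwhm(line_profile((0:4) * 10, rep(3, 5))), "flat")
  expect_error(fwhm(line_profile((0:4) * 10, c(0, 1, 2, 3, 4))),
               "crossing")
  expect_error(line_profile(c(0, 10, 15), c(1, 2, 1)), "uniform")
  expect_error(line_profile(c(0, -10, -20), c(1, 2, 1)), "increasing")
})

test_that("FWHM is invariant to intensity scaling and offsets", {
  pr <- gaussian_profile(sigma_nm = 80, spacing_nm = 5)
  w <- fwhm(pr)
  scaled <- line_profile(pr$positions, 7 * pr$intensities + 11)
  expect_equal(fwhm(scaled), w, tolerance = 1e-9)
})

test_that("binarization thresholds probabilities elementwise", {
  expect_true(all(binarize_mask(matrix(0.9, 3, 3)) == 1))
  expect_true(all(binarize_mask(matrix(0.1, 3, 3)) == 0))
  p <- matrix(c(0.2, 0.5, 0.7, 0.49, 0.51, 0, 1, 0.3), 4, 2)
  expect_equal(binarize_mask(p), (p >= 0.5) + 0)
  expect_error(binarize_mask(matrix(1.2, 2, 2)), "\\[0, 1\\]")
})

test_that("masking preserves inside pixels exactly and never increases", {
  img <- random_image(32, seed = 101)
  ones <- matrix(1, 32, 32)
  expect_identical(apply_mask(img, ones)$pixels, img$pixels)
  expect_true(all(apply_mask(img, 0 * ones)$pixels == 0))
  set.seed(102)
  mask <- (matrix(stats::runif(1024), 32, 32) > 0.5) + 0
  out <- apply_mask(img, mask)
  expect_identical(out$pixels[mask == 1], img$pixels[mask == 1])
  expect_true(all(out$pixels <= img$pixels))
  expect_error(apply_mask(img, matrix(1, 4, 4)), "mismatch")
})

test_that("identical images give SSIM 1 and the capped PSNR sentinel", {
  img <- random_image(32, seed = 103, bit_depth = 8L)
  m <- image_metrics(img, img)
  expect_equal(m[["ssim"]], 1, tolerance = 1e-9)
  expect_equal(m[["psnr"]], 100)
})

test_that("PSNR of a uniform +10 offset is 20 log10(255/10)", {
  base <- random_image(32, seed = 104, bit_depth = 8L)
  base$pixels <- pmin(base$pixels, 245)
  shifted <- intensity_image(base$pixels + 10, bit_depth = 8L)
  m <- image_metrics(shifted, base)
  expect_equal(m[["psnr"]], 20 * log10(255 / 10), tolerance = 1e-9)
})

test_that("inverted checkerboards score near-zero SSIM", {
  side <- 64
  cb <- (outer(1:side, 1:side, "+") %% 2) * 255
  a <- intensity_image(cb, bit_depth = 8L)
  b <- intensity_image(255 - cb, bit_depth = 8L)
  m <- image_metrics(a, b)
  expect_lt(m[["ssim"]], 0.1)
  expect_error(image_metrics(a, random_image(32, bit_depth = 8L)),
               "mismatch")
})

test_that("3D stacking keeps order, depth and the projection geometry", {
  slices <- lapply(1:5, function(i) random_image(16, seed = 110 + i))
  st <- stack_3d(slices, pitch_z = 250)
  expect_length(st$slices, 5)
  expect_equal(st$pitch_z, 250)
  f <- withr::local_tempfile(fileext = ".tif")
  write_tiff(st, f)
  back <- read_tiff(f)
  for (i in 1:5) expect_identical(back$slices[[i]]$pixels,
                                  slices[[i]]$pixels)
  # MIP of a one-bright-voxel stack lights exactly that xy position
  dark <- lapply(1:4, function(i) intensity_image(matrix(0, 8, 8)))
  dark[[3]]$pixels[5, 2] <- 4000
  mp <- max_projection(stack_3d(dark, 1000))
  expect_equal(mp$pixels[5, 2], 4000)
  expect_equal(sum(mp$pixels), 4000)
  bad <- c(slices, list(random_image(8, seed = 120)))
  expect_error(stack_3d(bad, 250), "differ")
})

test_that("tiled prediction is pure and assembles to input size", {
  cfg <- anet_config(input_side = 16, depth = 2, base_channels = 2)
  m <- anet_init(cfg, seed = 121)
  img <- random_image(32, seed = 122, bit_depth = 8L)
  pred <- predict_full(img, m)
  expect_equal(dim(pred), c(32, 32))
  expect_true(all(pred >= 0 & pred <= 1))
  # identical tiles -> identical predictions (purity)
  q <- img$pixels[1:16, 1:16]
  same <- intensity_image(rbind(cbind(q, q), cbind(q, q)),
                          bit_depth = 8L)
  pr <- predict_full(same, m)
  expect_equal(pr[1:16, 1:16], pr[17:32, 17:32], tolerance = 1e-12)
  expect_error(predict_full(random_image(24, bit_depth = 8L), m),
               "multiples")
})

test_that("perpendicular-cut widths recover the blur width on a phantom", {
  sc <- horizontal_scene()
  tr <- render_truth(sc)
  obs <- degrade(tr, noise = noise_model(gaussian_sigma = 0,
                                         poisson = FALSE, offset = 0),
                 seed = 1)
  w <- fwhm_perpendicular_cuts(obs, sc)
  expect_gte(length(w), 3)
  # blur FWHM = 2.355 * r_perp ~ 657 nm, broadened a little by the
  # 250 nm pixelation of the profile
  expect_true(all(w > 500 & w < 900))
})
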