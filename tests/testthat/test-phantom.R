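test_that("scene generation is reproducible and respects counts", {
  a <- generate_scene(4, seed = 11)
  b <- generate_scene(4, seed = 11)
  expect_identical(a, b)
  empty <- generate_scene(0, seed = 1)
  expect_length(empty$curves, 0)
  expect_error(generate_scene(3, field_nm = -1), "positive")
})

test_that("an empty scene degrades to pure background noise", {
  tr <- render_truth(generate_scene(0, seed = 1))
  expect_true(all(tr$intensity == 0))
  obs <- degrade(tr, noise = noise_model(gaussian_sigma = 5, offset = 50),
                 seed = 2)
  expect_true(abs(mean(obs$pixels) - 50) < 2)  # Poisson(50) + read noise
  expect_true(stats::sd(obs$pixels) > 0)
})

test_that("filament count equals connected components of the truth mask", {
  # brute-force 8-connected flood fill (curves step diagonally)
  count_components <- function(mask) {
    n <- 0L
    while (any(mask > 0)) {
      n <- n + 1L
      seed <- which(mask > 0, arr.ind = TRUE)[1, , drop = FALSE]
      comp <- matrix(FALSE, nrow(mask), ncol(mask))
      comp[seed] <- TRUE
      repeat {
        grown <- comp
        for (di in -1:1) for (dj in -1:1) {
          sh <- matrix(FALSE, nrow(comp), ncol(comp))
          ri <- pmin(pmax(seq_len(nrow(comp)) + di, 1), nrow(comp))
          ci <- pmin(pmax(seq_len(ncol(comp)) + dj, 1), ncol(comp))
          grown <- grown | comp[ri, ci]
        }
        grown <- grown & mask > 0
        if (identical(grown, comp)) break
        comp <- grown
      }
      mask[comp] <- 0
    }
    n
  }
  # a seed whose five curves do not cross (verified with this oracle)
  sc <- generate_scene(5, seed = 37)
  tr <- render_truth(sc, supersample_pitch_nm = 62.5)
  expect_equal(count_components(tr$mask), length(sc$curves))
  expect_equal(length(sc$curves), 5)
})

test_that("rendered truth integrates to amplitude * length / pitch", {
  sc <- generate_scene(3, seed = 31)
  tr <- render_truth(sc)
  len <- sum(vapply(sc$curves, anetsr:::curve_length_nm, numeric(1)))
  expect_equal(sum(tr$intensity), sc$amplitude * len / tr$pitch_nm,
               tolerance = 0.02)
})

test_that("a horizontal centerline renders one pixel wide at its length", {
  sc <- horizontal_scene()
  tr <- render_truth(sc)
  # all mask pixels in a single grid row, count = line length in px
  rows <- which(rowSums(tr$mask) > 0)
  expect_length(rows, 1)
  len_px <- round(anetsr:::curve_length_nm(sc$curves[[1]]) / tr$pitch_nm)
  expect_equal(sum(tr$mask), len_px, tolerance = 0.02)
})

test_that("a delta PSF with no noise and no binning is the identity", {
  sc <- generate_scene(2, seed = 5)
  tr <- render_truth(sc)
  quiet <- noise_model(gaussian_sigma = 0, poisson = FALSE, offset = 0)
  # a wavelength this short gives sigma = 0.5 nm << pitch: a delta kernel
  obs <- degrade(list(intensity = tr$intensity, pitch_nm = tr$pitch_nm),
                 optical = optical_model(lambda_e = 0.25 * 2 * 1.4 / 0.61),
                 noise = quiet, out_pitch_nm = tr$pitch_nm, seed = 1)
  expect_equal(obs$pixels, round(tr$intensity), tolerance = 1e-6)
})

test_that("flux is conserved by blur + binning for interior signal", {
  sc <- horizontal_scene(margin = 0.3)
  tr <- render_truth(sc)
  quiet <- noise_model(gaussian_sigma = 0, poisson = FALSE, offset = 0)
  obs <- degrade(tr, noise = quiet, seed = 1)
  expect_equal(sum(obs$pixels), sum(tr$intensity), tolerance = 0.005)
})

test_that("degradation is linear in amplitude when noise is off", {
  sc <- generate_scene(2, seed = 8)
  tr <- render_truth(sc)
  quiet <- noise_model(gaussian_sigma = 0, poisson = FALSE, offset = 0)
  a <- degrade(tr, noise = quiet, seed = 1)
  tr2 <- tr; tr2$intensity <- 3 * tr$intensity
  b <- degrade(tr2, noise = quiet, seed = 1)
  # quantization allows at most 1-count rounding differences per pixel
  expect_true(max(abs(b$pixels - 3 * a$pixels)) <= 2)
})

test_that("Poisson shot noise is unbiased at a bright pixel", {
  sc <- horizontal_scene(field_nm = 8000)
  tr <- render_truth(sc)
  quiet <- noise_model(gaussian_sigma = 0, poisson = FALSE, offset = 0)
  noiseless <- degrade(tr, noise = quiet, seed = 1)
  px <- which(noiseless$pixels == max(noiseless$pixels),
              arr.ind = TRUE)[1, ]
  shot <- noise_model(gaussian_sigma = 0, poisson = TRUE, offset = 0)
  reps <- vapply(1:500, function(i)
    degrade(tr, noise = shot, seed = 1000 + i)$pixels[px[1], px[2]],
    numeric(1))
  mu <- noiseless$pixels[px[1], px[2]]
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(reps) - mu), 3 * se)
})

test_that("the brightest observed pixel tracks the true centerline", {
  sc <- horizontal_scene()
  tr <- render_truth(sc)
  quiet <- noise_model(gaussian_sigma = 0, poisson = FALSE, offset = 0)
  obs <- degrade(tr, noise = quiet, seed = 1)
  cfg <- phantom_config()
  true_row <- floor(sc$curves[[1]][1, 1] / obs$pitch_xy) + 1
  cols <- which(colSums(obs$pixels) > 0)
  cols <- cols[cols > 10 & cols < 54]  # interior cuts only
  for (j in cols[seq(1, length(cols), by = 5)]) {
    expect_lte(abs(which.max(obs$pixels[, j]) - true_row), 1)
  }
})

test_that("dataset generation is seed-deterministic down to bytes", {
  cfg <- phantom_config(image_px = 32)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ds1 <- make_dataset(2, 1, cfg, seed = 5, dir = d1, force = TRUE)
  ds2 <- make_dataset(2, 1, cfg, seed = 5, dir = d2, force = TRUE)
  expect_equal(nrow(ds1$manifest), 3)
  for (f in ds1$manifest$observed) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # refuses to clobber an existing dataset without force
  expect_error(make_dataset(2, 1, cfg, seed = 5, dir = d1), "force")
})
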