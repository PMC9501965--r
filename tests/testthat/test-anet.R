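test_that("bottleneck spatial side follows the /2^depth arithmetic", {
  expect_equal(feature_shape(512, 4), 32)
  expect_equal(feature_shape(2048, 4), 128)
  expect_equal(feature_shape(16, 4), 1)
  # bottleneck storage grows 16x from 512- to 2048-scale input
  expect_equal((feature_shape(2048, 4) / feature_shape(512, 4))^2, 16)
  expect_error(feature_shape(100, 4), "divisible")
})

test_that("pixel softmax normalizes, is symmetric, and matches hand values", {
  for (c0 in c(-3, 0, 7)) {
    a <- array(c0, c(2, 2, 2))
    P <- pixel_softmax(a)
    expect_equal(as.numeric(P), rep(0.5, 8))
  }
  a <- array(0, c(1, 1, 2)); a[1, 1, 1] <- log(2)
  expect_equal(as.numeric(pixel_softmax(a)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  set.seed(61)
  a <- array(rnorm(4 * 4 * 3, 0, 5), c(4, 4, 3))
  P <- pixel_softmax(a)
  expect_equal(apply(P, c(1, 2), sum), matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("stabilized softmax agrees with the direct formula for |a| <= 20", {
  set.seed(62)
  for (r in 1:5) {
    a <- array(stats::runif(3 * 3 * 2, -20, 20), c(3, 3, 2))
    direct <- exp(a)
    direct <- direct / array(rep(apply(direct, c(1, 2), sum), 2), dim(a))
    expect_equal(pixel_softmax(a), direct, tolerance = 1e-6)
  }
  # and it survives activations that overflow exp()
  a <- array(c(1000, 999), c(1, 1, 2))
  expect_equal(as.numeric(pixel_softmax(a)),
               c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))),
               tolerance = 1e-9)
})

test_that("weighted cross-entropy is zero at perfection and linear in omega", {
  g <- matrix(c(0, 1, 1, 0), 2, 2)
  P <- array(0, c(2, 2, 2))
  P[, , 1] <- (g == 0) + 0; P[, , 2] <- (g == 1) + 0
  wm <- list(omega = matrix(2, 2, 2), g = g)
  expect_equal(weighted_cross_entropy(P, wm), 0)
  # single pixel, omega = 1, P_g = exp(-1) -> E = 1
  P1 <- array(c(exp(-1), 1 - exp(-1)), c(1, 1, 2))
  expect_equal(weighted_cross_entropy(
    P1, list(omega = matrix(1, 1, 1), g = matrix(0, 1, 1))), 1,
    tolerance = 1e-12)
  # scaling omega scales E
  set.seed(63)
  a <- array(rnorm(8), c(2, 2, 2))
  P <- pixel_softmax(a)
  wm1 <- list(omega = matrix(stats::runif(4), 2, 2), g = g)
  wm3 <- list(omega = 3 * wm1$omega, g = g)
  expect_equal(weighted_cross_entropy(P, wm3),
               3 * weighted_cross_entropy(P, wm1), tolerance = 1e-12)
  expect_gt(weighted_cross_entropy(P, wm1), 0)
  expect_error(weighted_cross_entropy(P, list(omega = matrix(1, 3, 3),
                                              g = matrix(0, 3, 3))),
               "mismatch")
})

test_that("loss gradient w.r.t. activations matches finite differences", {
  set.seed(64)
  a <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  g <- matrix(sample(0:1, 16, TRUE), 4, 4)
  wm <- compute_weight_map(g)
  grad <- anetsr:::ce_activation_grad(pixel_softmax(a), wm)
  h <- 1e-6
  for (i in sample(length(a), 12)) {
    ap <- a; ap[i] <- ap[i] + h
    am <- a; am[i] <- am[i] - h
    fd <- (weighted_cross_entropy(pixel_softmax(ap), wm) -
             weighted_cross_entropy(pixel_softmax(am), wm)) / (2 * h)
    expect_equal(grad[i], fd, tolerance = 1e-4)
  }
})

test_that("weight maps emphasize boundaries and match a brute-force oracle", {
  # 8x8 label with one 2-px strip
  g <- matrix(0, 8, 8); g[4:5, ] <- 1
  wm <- compute_weight_map(g, w0 = 10, sigma = 5)
  # brute force: distance from each pixel to the nearest boundary pixel
  bnd <- which(g != rbind(g[-1, ], g[8, ]) | g != rbind(g[1, ], g[-8, ]),
               arr.ind = TRUE)
  f1 <- mean(g)
  wc <- ifelse(g == 1, 0.5 / f1, 0.5 / (1 - f1))
  expected <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    d <- sqrt(min((bnd[, 1] - i)^2 + (bnd[, 2] - j)^2))
    expected[i, j] <- wc[i, j] + 10 * exp(-d^2 / 50)
  }
  expect_equal(wm$omega, expected, tolerance = 1e-6)
  # monotone: boundary-adjacent weight >= weight far away (same class)
  expect_gte(wm$omega[3, 4], wm$omega[1, 4])
})

test_that("a boundary-free label reduces to the class-balance term", {
  wm <- compute_weight_map(matrix(0, 6, 6))
  expect_true(all(wm$omega == wm$omega[1, 1]))
  expect_equal(wm$omega[1, 1], 0.5)  # background frequency 1
})

test_that("same convolutions keep spatial size through the network", {
  cfg <- anet_config(input_side = 64, depth = 2, base_channels = 4)
  m <- anet_init(cfg, seed = 71)
  P <- anet_forward(m, matrix(stats::runif(64 * 64), 64, 64))
  expect_equal(dim(P), c(64, 64, 2))
  P2 <- anet_forward(m, matrix(stats::runif(32 * 32), 32, 32))
  expect_equal(dim(P2), c(32, 32, 2))  # any divisible size works
  expect_error(anet_forward(m, matrix(0.5, 30, 30)), "divisible")
})

test_that("encoder and decoder maps at matching levels share sizes", {
  cfg <- anet_config(input_side = 32, depth = 3, base_channels = 2)
  m <- anet_init(cfg, seed = 72)
  fw <- anetsr:::anet_forward_full(m, matrix(stats::runif(1024), 32, 32),
                                   train = FALSE)
  for (k in 1:3) {
    # the decoder cached the concatenation: its skip half came from the
    # encoder map of the same level without any cropping
    expect_equal(fw$caches$dec[[k]]$nskip, cfg$base_channels * 2^(k - 1))
  }
  expect_equal(dim(fw$P)[1:2], c(32, 32))
})

test_that("network gradients match finite differences end to end", {
  cfg <- anet_config(input_side = 8, depth = 1, base_channels = 2)
  m <- anet_init(cfg, seed = 73)
  set.seed(74)
  x <- matrix(stats::runif(64), 8, 8)
  g <- matrix(sample(0:1, 64, TRUE), 8, 8)
  wm <- compute_weight_map(g)
  fw <- anetsr:::anet_forward_full(m, x, train = TRUE)
  grads <- anetsr:::anet_backward(m, fw,
                                  anetsr:::ce_activation_grad(fw$P, wm))
  loss_at <- function(model) {
    f <- anetsr:::anet_forward_full(model, x, train = TRUE)
    weighted_cross_entropy(f$P, wm)
  }
  h <- 1e-5
  spots <- list(
    list(g = grads$enc[[1]]$c1$W,
         set = function(m, v) { m$params$enc[[1]]$c1$W <- v; m },
         get = function(m) m$params$enc[[1]]$c1$W),
    list(g = grads$bott$b1$gamma,
         set = function(m, v) { m$params$bott$b1$gamma <- v; m },
         get = function(m) m$params$bott$b1$gamma),
    list(g = grads$dec[[1]]$up$W,
         set = function(m, v) { m$params$dec[[1]]$up$W <- v; m },
         get = function(m) m$params$dec[[1]]$up$W),
    list(g = grads$out$W,
         set = function(m, v) { m$params$out$W <- v; m },
         get = function(m) m$params$out$W))
  set.seed(75)
  for (sp in spots) {
    for (i in sample(length(sp$g), 3)) {
      mp <- m; v <- sp$get(mp); v[i] <- v[i] + h; mp <- sp$set(mp, v)
      mm <- m; v <- sp$get(mm); v[i] <- v[i] - h; mm <- sp$set(mm, v)
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      expect_equal(sp$g[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("training overfits a single tile pair", {
  sc <- generate_scene(3, seed = 81)
  obs <- degrade(render_truth(sc), seed = 82)
  lab <- make_label(threshold_denoise(obs))
  pair <- list(x = convert_16_to_8(obs, minmax = TRUE), g = lab$pixels)
  cfg <- anet_config(input_side = 64, depth = 2, base_channels = 8)
  m <- anet_train(list(pair), cfg,
                  train_config(epochs = 200, lr = 1e-2, seed = 83),
                  augment = FALSE)
  pred <- anet_predict(m, pair$x)
  acc <- mean((pred >= 0.5) == (pair$g == 1))
  expect_gt(acc, 0.99)
  expect_true(all(diff(m$log$loss[c(1, 50, 200)]) < 0))
})

test_that("zero epochs returns the initialized model untouched", {
  cfg <- anet_config(input_side = 16, depth = 2, base_channels = 2)
  pair <- list(x = matrix(0.5, 16, 16), g = matrix(0, 16, 16))
  ref <- anet_init(cfg, seed = 0)
  m <- anet_train(list(pair), cfg, train_config(epochs = 0, seed = 0))
  expect_equal(m$params, ref$params)
  expect_equal(nrow(m$log), 0)
  expect_error(anet_train(list(), cfg), "empty")
})

test_that("the reference training schedule passes config validation", {
  tc <- train_config(epochs = 200, batch = 1)
  expect_equal(tc$epochs, 200L)
  expect_equal(tc$batch, 1L)
  expect_error(train_config(batch = 4), "minibatch")
  expect_error(train_config(epochs = -1), ">= 0")
  cfg <- anet_config(input_side = 512, depth = 4, base_channels = 64)
  expect_equal(cfg$base_channels * 2^cfg$depth, 1024)  # bottleneck width
  expect_error(anet_config(input_side = 100, depth = 4), "divisible")
})

test_that("training is bit-reproducible under a fixed seed", {
  sc <- generate_scene(2, seed = 91)
  obs <- degrade(render_truth(sc), seed = 92)
  lab <- make_label(threshold_denoise(obs))
  pair <- list(x = convert_16_to_8(obs, minmax = TRUE), g = lab$pixels)
  cfg <- anet_config(input_side = 64, depth = 2, base_channels = 4)
  m1 <- anet_train(list(pair), cfg, train_config(epochs = 3, seed = 93))
  m2 <- anet_train(list(pair), cfg, train_config(epochs = 3, seed = 93))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
})
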