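# Building blocks of the A-net, implemented on [H, W, C] numeric arrays
# with im2col + BLAS matrix products. All 3x3 convolutions are "same"
# (zero-padded), so spatial size is preserved everywhere and encoder
# feature maps concatenate onto decoder maps without cropping.

# cached im2col index table for 3x3 same convolution on an H x W grid;
# entries are linear pixel indices, NA outside the image (zero pad)
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W) {
  key <- paste0(H, "x", W)
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(NA_integer_, H * W, 9L)
  o <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      o <- o + 1L
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      v <- rep(NA_integer_, H * W)
      v[ok] <- (jj[ok] - 1L) * H + ii[ok]
      idx[, o] <- v
    }
  }
  .im2col_cache[[key]] <- idx
  idx
}

# x: [H,W,C] -> (H*W) x (9*C); column block for channel c is
# (c-1)*9 + offset, matching the weight-matrix row layout
im2col <- function(x) {
  d <- dim(x)
  idx <- im2col_idx(d[1L], d[2L])
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  out <- matrix(0, d[1L] * d[2L], 9L * d[3L])
  cols <- (seq_len(d[3L]) - 1L) * 9L
  for (o in 1:9) {
    src <- idx[, o]
    ok <- !is.na(src)
    out[ok, cols + o] <- xm[src[ok], , drop = FALSE]
  }
  out
}

col2im <- function(dX2, H, W, C) {
  idx <- im2col_idx(H, W)
  dxm <- matrix(0, H * W, C)
  cols <- (seq_len(C) - 1L) * 9L
  for (o in 1:9) {
    src <- idx[, o]
    ok <- !is.na(src)
    dxm[src[ok], ] <- dxm[src[ok], , drop = FALSE] +
      dX2[ok, cols + o, drop = FALSE]
  }
  array(dxm, c(H, W, C))
}

conv_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))),
                  9L * cin, cout),
       b = numeric(cout))
}

conv_fw <- function(x, p) {
  d <- dim(x)
  X2 <- im2col(x)
  Y <- X2 %*% p$W
  Y <- sweep(Y, 2L, p$b, "+")
  list(y = array(Y, c(d[1L], d[2L], ncol(p$W))),
       cache = list(X2 = X2, d = d))
}

conv_bw <- function(dy, p, cache) {
  dY <- matrix(dy, prod(dim(dy)[1:2]), dim(dy)[3L])
  dW <- crossprod(cache$X2, dY)
  db <- colSums(dY)
  dX2 <- dY %*% t(p$W)
  dx <- col2im(dX2, cache$d[1L], cache$d[2L], cache$d[3L])
  list(dx = dx, grad = list(W = dW, b = db))
}

bn_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# spatial batch normalization (minibatch 1: statistics over H*W per
# channel); running estimates are kept for inference
bn_fw <- function(x, p, run, train) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc^2)
    run$mean <- (1 - BN_MOMENTUM) * run$mean + BN_MOMENTUM * mu
    run$var <- (1 - BN_MOMENTUM) * run$var + BN_MOMENTUM * va
  } else {
    mu <- run$mean
    xc <- sweep(xm, 2L, mu)
    va <- run$var
  }
  inv_sd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(xc, 2L, inv_sd, "*")
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(y = array(y, d),
       cache = list(xhat = xhat, inv_sd = inv_sd, d = d))
}

bn_bw <- function(dy, p, cache) {
  d <- cache$d
  N <- d[1L] * d[2L]
  dym <- matrix(dy, N, d[3L])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, p$gamma, "*")
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / N)
  t2 <- sweep(cache$xhat, 2L, colSums(dxhat * cache$xhat) / N, "*")
  dx <- sweep(t1 - t2, 2L, cache$inv_sd, "*")
  list(dx = array(dx, d), grad = list(gamma = dgamma, beta = dbeta))
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bw <- function(dy, cache) dy * cache

# 2x2 max pooling, stride 2; ties go to the first window position
pool_fw <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1L], 2L); ci <- seq(1L, d[2L], 2L)
  a <- x[ri, ci, , drop = FALSE]; b <- x[ri + 1L, ci, , drop = FALSE]
  cc <- x[ri, ci + 1L, , drop = FALSE]; e <- x[ri + 1L, ci + 1L, , drop = FALSE]
  y <- pmax(a, b, cc, e)
  ma <- a == y; mb <- b == y & !ma
  mc <- cc == y & !ma & !mb; me <- !ma & !mb & !mc
  list(y = y, cache = list(ma = ma, mb = mb, mc = mc, me = me, d = d))
}

pool_bw <- function(dy, cache) {
  d <- cache$d
  dx <- array(0, d)
  ri <- seq(1L, d[1L], 2L); ci <- seq(1L, d[2L], 2L)
  dx[ri, ci, ] <- dy * cache$ma
  dx[ri + 1L, ci, ] <- dy * cache$mb
  dx[ri, ci + 1L, ] <- dy * cache$mc
  dx[ri + 1L, ci + 1L, ] <- dy * cache$me
  dx
}

upconv_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * 4L * cout, 0, sqrt(2 / cin)),
                  cin, 4L * cout),
       b = numeric(cout))
}

# 2x2 transposed convolution, stride 2: each input pixel paints a
# disjoint 2x2 output block, so no overlap-add is needed
upconv_fw <- function(x, p) {
  d <- dim(x)
  cout <- length(p$b)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  Y <- xm %*% p$W
  out <- array(0, c(2L * d[1L], 2L * d[2L], cout))
  ri <- seq(1L, 2L * d[1L], 2L); ci <- seq(1L, 2L * d[2L], 2L)
  for (co in seq_len(cout)) {
    base <- (co - 1L) * 4L
    out[ri, ci, co] <- matrix(Y[, base + 1L], d[1L], d[2L])
    out[ri + 1L, ci, co] <- matrix(Y[, base + 2L], d[1L], d[2L])
    out[ri, ci + 1L, co] <- matrix(Y[, base + 3L], d[1L], d[2L])
    out[ri + 1L, ci + 1L, co] <- matrix(Y[, base + 4L], d[1L], d[2L])
    out[, , co] <- out[, , co] + p$b[co]
  }
  list(y = out, cache = list(xm = xm, d = d, cout = cout))
}

upconv_bw <- function(dy, p, cache) {
  d <- cache$d; cout <- cache$cout
  ri <- seq(1L, 2L * d[1L], 2L); ci <- seq(1L, 2L * d[2L], 2L)
  dY <- matrix(0, d[1L] * d[2L], 4L * cout)
  db <- numeric(cout)
  for (co in seq_len(cout)) {
    base <- (co - 1L) * 4L
    dY[, base + 1L] <- as.numeric(dy[ri, ci, co])
    dY[, base + 2L] <- as.numeric(dy[ri + 1L, ci, co])
    dY[, base + 3L] <- as.numeric(dy[ri, ci + 1L, co])
    dY[, base + 4L] <- as.numeric(dy[ri + 1L, ci + 1L, co])
    db[co] <- sum(dy[, , co])
  }
  dW <- crossprod(cache$xm, dY)
  dx <- array(dY %*% t(p$W), d)
  list(dx = dx, grad = list(W = dW, b = db))
}

out_init <- function(cin, M) {
  list(W = matrix(stats::rnorm(cin * M, 0, sqrt(2 / cin)), cin, M),
       b = numeric(M))
}

# final 1x1 convolution to M class-activation channels
out_fw <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  Y <- sweep(xm %*% p$W, 2L, p$b, "+")
  list(y = array(Y, c(d[1L], d[2L], ncol(p$W))),
       cache = list(xm = xm, d = d))
}

out_bw <- function(dy, p, cache) {
  dY <- matrix(dy, prod(dim(dy)[1:2]), dim(dy)[3L])
  list(dx = array(dY %*% t(p$W), cache$d),
       grad = list(W = crossprod(cache$xm, dY), b = colSums(dY)))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
  out[, , seq_len(da[3L])] <- a
  out[, , da[3L] + seq_len(db[3L])] <- b
  out
}
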