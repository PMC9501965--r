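#' A-net architecture configuration
#'
#' The A-net is a U-net variant in which every valid convolution is
#' replaced by a same convolution, so encoder and decoder feature maps
#' at matching levels have identical spatial size and skip connections
#' concatenate without cropping, and the output has the size of the
#' input. Encoder block k (0-based) carries `base_channels * 2^k`
#' channels; the bottleneck carries `base_channels * 2^depth` (1024 for
#' the default depth-4, 64-channel network).
#'
#' @param input_side input tile side in px; must be divisible by
#'   `2^depth`.
#' @param depth number of encoder blocks.
#' @param base_channels channels of the first block.
#' @param classes number of output categories M (>= 2; 2 for
#'   filament/background).
#' @return a list of class `anet_config`.
#' @export
anet_config <- function(input_side = 512, depth = 4, base_channels = 64,
                        classes = 2) {
  depth <- as.integer(depth)
  if (depth < 1) stop("`depth` must be >= 1")
  if (classes < 2) stop("`classes` must be >= 2")
  if (input_side %% 2^depth != 0)
    stop("`input_side` must be divisible by 2^depth")
  structure(list(input_side = as.integer(input_side), depth = depth,
                 base_channels = as.integer(base_channels),
                 classes = as.integer(classes)),
            class = "anet_config")
}

#' Bottleneck spatial side
#'
#' Spatial side of the deepest feature map: `input_side / 2^depth`
#' (32 for a 512 input at depth 4, 128 for a 2048 input).
#'
#' @param input_side input side in px.
#' @param depth encoder depth.
#' @return integer spatial side.
#' @export
feature_shape <- function(input_side, depth) {
  if (input_side %% 2^depth != 0)
    stop("`input_side` must be divisible by 2^depth")
  as.integer(input_side %/% 2^depth)
}

#' Pixel-wise softmax over class channels
#'
#' `P_i(x) = exp(a_i(x)) / sum_j exp(a_j(x))`, stabilized by
#' subtracting the per-pixel maximum activation, so probabilities sum
#' to one at every pixel for arbitrarily large activations.
#'
#' @param a numeric `[H, W, M]` array of class activations (M >= 2).
#' @return `[H, W, M]` array of probabilities.
#' @export
pixel_softmax <- function(a) {
  d <- dim(a)
  if (length(d) != 3L || d[3L] < 2L)
    stop("`a` must be an [H, W, M] array with M >= 2")
  am <- matrix(a, d[1L] * d[2L], d[3L])
  mx <- am[, 1L]
  for (j in 2:d[3L]) mx <- pmax(mx, am[, j])
  e <- exp(am - mx)
  array(e / rowSums(e), d)
}

#' Boundary-emphasizing weight map
#'
#' Per-pixel loss weights `omega(x) = w_class(g(x)) +
#' w0 * exp(-d(x)^2 / (2 sigma^2))`, where `d(x)` is the Euclidean
#' distance to the nearest label boundary and `w_class` balances the
#' two classes by inverse frequency (normalized so balanced classes get
#' weight 1, capped at 50 for near-empty classes). A label with no
#' boundary yields the class-balance term alone. The map is computed
#' once per label, before training.
#'
#' @param label binary matrix (or 0/1 [intensity_image]).
#' @param w0 boundary emphasis amplitude (default 10).
#' @param sigma boundary emphasis length scale in px (default 5).
#' @return object of class `weight_map`: list with `omega` (weights)
#'   and `g` (0/1 ground-truth matrix).
#' @export
compute_weight_map <- function(label, w0 = 10, sigma = 5) {
  if (inherits(label, "intensity_image")) label <- label$pixels
  if (!all(label %in% c(0, 1))) stop("`label` must be binary")
  g <- (label > 0) + 0
  f1 <- mean(g)
  wc1 <- min(0.5 / max(f1, 1e-9), 50)
  wc0 <- min(0.5 / max(1 - f1, 1e-9), 50)
  wc <- ifelse(g == 1, wc1, wc0)
  H <- nrow(g); W <- ncol(g)
  # boundary pixels: differ from any 4-neighbour
  bnd <- matrix(FALSE, H, W)
  if (H > 1L) {
    dif <- g[-1L, ] != g[-H, ]
    bnd[-H, ] <- bnd[-H, ] | dif; bnd[-1L, ] <- bnd[-1L, ] | dif
  }
  if (W > 1L) {
    dif <- g[, -1L] != g[, -W]
    bnd[, -W] <- bnd[, -W] | dif; bnd[, -1L] <- bnd[, -1L] | dif
  }
  omega <- if (!any(bnd)) {
    wc
  } else {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - bnd)))
    wc + w0 * exp(-d^2 / (2 * sigma^2))
  }
  structure(list(omega = omega, g = g), class = "weight_map")
}

#' Boundary-weighted cross-entropy loss
#'
#' `E = -sum_x omega(x) log P_{g(x)}(x)`: the negative log-likelihood
#' of the ground-truth class under the softmax output, weighted per
#' pixel. E >= 0, with E = 0 exactly when the true-class probability is
#' 1 wherever the weight is positive, and E scales linearly in omega.
#'
#' @param P `[H, W, M]` probability array from [pixel_softmax()].
#' @param weight_map a [compute_weight_map()] result (fields `omega`,
#'   `g` with classes in 0..M-1).
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(P, weight_map) {
  d <- dim(P)
  if (!identical(dim(weight_map$g), d[1:2]))
    stop("shape mismatch between P and weight map")
  pm <- matrix(P, d[1L] * d[2L], d[3L])
  gi <- as.integer(weight_map$g) + 1L
  sel <- pm[cbind(seq_along(gi), gi)]
  -sum(as.numeric(weight_map$omega) * log(sel))
}

# the 8 dihedral transforms of a square matrix (op in 0..7)
dihedral <- function(m, op) {
  if (op >= 4L) m <- m[nrow(m):1L, , drop = FALSE]
  for (r in seq_len(op %% 4L)) m <- t(m[nrow(m):1L, , drop = FALSE])
  m
}

# gradient of the loss w.r.t. the activations: omega * (P - onehot(g))
ce_activation_grad <- function(P, weight_map) {
  d <- dim(P)
  pm <- matrix(P, d[1L] * d[2L], d[3L])
  gi <- as.integer(weight_map$g) + 1L
  pm[cbind(seq_along(gi), gi)] <- pm[cbind(seq_along(gi), gi)] - 1
  array(pm * as.numeric(weight_map$omega), d)
}

# ---- model assembly -------------------------------------------------

block_init <- function(cin, cout) {
  list(c1 = conv_init(cin, cout), b1 = bn_init(cout),
       c2 = conv_init(cout, cout), b2 = bn_init(cout))
}

new_bn_state <- function(c) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, c); e$var <- rep(1, c)
  e
}

#' Initialize an A-net model
#'
#' He-initialized weights; batch-norm scale 1 / shift 0. The returned
#' model carries its configuration, parameters and running batch-norm
#' statistics.
#'
#' @param config an [anet_config].
#' @param seed RNG seed (`NULL`: current stream).
#' @return a list of class `anet_model`.
#' @export
anet_init <- function(config = anet_config(), seed = NULL) {
  with_seed(seed, {
    depth <- config$depth
    ch <- config$base_channels * 2^(seq_len(depth) - 1L)
    ch_bott <- config$base_channels * 2^depth
    params <- list(enc = vector("list", depth),
                   dec = vector("list", depth))
    stats <- new.env(parent = emptyenv())
    prev <- 1L
    for (k in seq_len(depth)) {
      params$enc[[k]] <- block_init(prev, ch[k])
      stats[[paste0("enc", k, "_1")]] <- new_bn_state(ch[k])
      stats[[paste0("enc", k, "_2")]] <- new_bn_state(ch[k])
      prev <- ch[k]
    }
    params$bott <- block_init(ch[depth], ch_bott)
    stats[["bott_1"]] <- new_bn_state(ch_bott)
    stats[["bott_2"]] <- new_bn_state(ch_bott)
    for (k in rev(seq_len(depth))) {
      above <- if (k == depth) ch_bott else ch[k + 1L]
      params$dec[[k]] <- c(list(up = upconv_init(above, ch[k])),
                           block_init(2L * ch[k], ch[k]))
      stats[[paste0("dec", k, "_1")]] <- new_bn_state(ch[k])
      stats[[paste0("dec", k, "_2")]] <- new_bn_state(ch[k])
    }
    params$out <- out_init(ch[1L], config$classes)
    structure(list(config = config, params = params, stats = stats),
              class = "anet_model")
  })
}

block_fw <- function(x, bp, stats, name, train) {
  r1 <- conv_fw(x, bp$c1)
  n1 <- bn_fw(r1$y, bp$b1, stats[[paste0(name, "_1")]], train)
  a1 <- relu_fw(n1$y)
  r2 <- conv_fw(a1$y, bp$c2)
  n2 <- bn_fw(r2$y, bp$b2, stats[[paste0(name, "_2")]], train)
  a2 <- relu_fw(n2$y)
  list(y = a2$y,
       cache = list(c1 = r1$cache, b1 = n1$cache, r1 = a1$cache,
                    c2 = r2$cache, b2 = n2$cache, r2 = a2$cache))
}

block_bw <- function(dy, bp, cache) {
  dy <- relu_bw(dy, cache$r2)
  b2 <- bn_bw(dy, bp$b2, cache$b2)
  c2 <- conv_bw(b2$dx, bp$c2, cache$c2)
  dy <- relu_bw(c2$dx, cache$r1)
  b1 <- bn_bw(dy, bp$b1, cache$b1)
  c1 <- conv_bw(b1$dx, bp$c1, cache$c1)
  list(dx = c1$dx,
       grads = list(c1 = c1$grad, b1 = b1$grad,
                    c2 = c2$grad, b2 = b2$grad))
}

#' Forward pass of the A-net
#'
#' Runs a tile through the encoder-decoder and returns the per-class
#' probability map. Same convolutions keep every feature map at the
#' spatial size dictated purely by pooling, so the output has exactly
#' the input's spatial size and skip maps are concatenated uncropped.
#'
#' @param model an [anet_model].
#' @param x input tile: `[H, W]` matrix with values in `[0, 1]`, or an
#'   [intensity_image] (normalized by its bit depth). H and W must be
#'   divisible by `2^depth`.
#' @param train logical; training mode uses per-tile batch statistics
#'   (and updates the running ones), inference mode uses the running
#'   statistics.
#' @return `[H, W, M]` probability array.
#' @export
anet_forward <- function(model, x, train = FALSE) {
  anet_forward_full(model, x, train)$P
}

anet_forward_full <- function(model, x, train) {
  if (inherits(x, "intensity_image")) x <- x$pixels / (2^x$bit_depth - 1)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  if (any(d[1:2] %% 2^model$config$depth != 0))
    stop("input sides must be divisible by 2^depth")
  p <- model$params; depth <- model$config$depth
  skips <- vector("list", depth)
  cc <- list(enc = vector("list", depth), dec = vector("list", depth))
  h <- x
  for (k in seq_len(depth)) {
    r <- block_fw(h, p$enc[[k]], model$stats, paste0("enc", k), train)
    skips[[k]] <- r$y
    pl <- pool_fw(r$y)
    h <- pl$y
    cc$enc[[k]] <- list(block = r$cache, pool = pl$cache)
  }
  r <- block_fw(h, p$bott, model$stats, "bott", train)
  h <- r$y
  cc$bott <- r$cache
  for (k in rev(seq_len(depth))) {
    u <- upconv_fw(h, p$dec[[k]]$up)
    merged <- concat_ch(skips[[k]], u$y)
    r <- block_fw(merged, p$dec[[k]], model$stats, paste0("dec", k), train)
    h <- r$y
    cc$dec[[k]] <- list(up = u$cache, nskip = dim(skips[[k]])[3L],
                        block = r$cache)
  }
  o <- out_fw(h, p$out)
  cc$out <- o$cache
  list(a = o$y, P = pixel_softmax(o$y), caches = cc)
}

anet_backward <- function(model, fw, da) {
  p <- model$params; depth <- model$config$depth
  cc <- fw$caches
  grads <- list(enc = vector("list", depth),
                dec = vector("list", depth))
  ob <- out_bw(da, p$out, cc$out)
  grads$out <- ob$grad
  dh <- ob$dx
  dskip <- vector("list", depth)
  for (k in seq_len(depth)) {
    bb <- block_bw(dh, p$dec[[k]], cc$dec[[k]]$block)
    ns <- cc$dec[[k]]$nskip
    dcat <- bb$dx
    dskip[[k]] <- dcat[, , seq_len(ns), drop = FALSE]
    du <- dcat[, , ns + seq_len(dim(dcat)[3L] - ns), drop = FALSE]
    ub <- upconv_bw(du, p$dec[[k]]$up, cc$dec[[k]]$up)
    grads$dec[[k]] <- c(list(up = ub$grad), bb$grads)
    dh <- ub$dx
  }
  bb <- block_bw(dh, p$bott, cc$bott)
  grads$bott <- bb$grads
  dh <- bb$dx
  for (k in rev(seq_len(depth))) {
    dpool <- pool_bw(dh, cc$enc[[k]]$pool)
    bb <- block_bw(dpool + dskip[[k]], p$enc[[k]], cc$enc[[k]]$block)
    grads$enc[[k]] <- bb$grads
    dh <- bb$dx
  }
  grads
}

# ---- Adam -----------------------------------------------------------

adam_new <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else p * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# deep snapshot of the running batch-norm statistics
snapshot_stats <- function(stats) {
  out <- list()
  for (nm in ls(stats)) out[[nm]] <- list(mean = stats[[nm]]$mean,
                                          var = stats[[nm]]$var)
  out
}

restore_stats <- function(snap) {
  e <- new.env(parent = emptyenv())
  for (nm in names(snap)) {
    s <- new.env(parent = emptyenv())
    s$mean <- snap[[nm]]$mean; s$var <- snap[[nm]]$var
    e[[nm]] <- s
  }
  e
}

#' Training-run configuration
#'
#' Validates the optimization settings; the reference regime is 200
#' epochs with minibatch 1 under Adam, and scaled studies use fewer
#' epochs at smaller tile sizes.
#'
#' @param epochs number of passes over the training pairs (>= 0).
#' @param batch minibatch size (only 1 is supported).
#' @param lr initial Adam learning rate.
#' @param lr_decay multiplicative decay applied at 1/3 and 2/3 of the
#'   schedule (1 disables; default 0.3), which damps the late-training
#'   noise of minibatch-1 updates.
#' @param seed integer seed controlling initialization and data order.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch = 1, lr = 3e-3,
                         lr_decay = 0.3, seed = 0) {
  if (epochs < 0) stop("`epochs` must be >= 0")
  if (batch != 1) stop("only minibatch size 1 is supported")
  if (lr <= 0) stop("`lr` must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stop("`lr_decay` must be in (0, 1]")
  structure(list(epochs = as.integer(epochs), batch = 1L, lr = lr,
                 lr_decay = lr_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Train an A-net on paired tiles
#'
#' Stochastic training with minibatch 1 under Adam, minimizing the
#' boundary-weighted cross-entropy. Weight maps are precomputed once
#' per label. A single seed controls initialization and the per-epoch
#' shuffling, so runs are bit-reproducible. The model state with the
#' lowest validation loss (training loss when no validation pairs are
#' given) is kept and returned.
#'
#' @param pairs list of training pairs `list(x = , g = )` where `x` is
#'   an [intensity_image] or a `[0, 1]` matrix and `g` a binary label
#'   matrix.
#' @param config an [anet_config].
#' @param train_cfg a [train_config].
#' @param val optional list of validation pairs in the same format.
#' @param w0,sigma_w weight-map constants (see [compute_weight_map()]).
#' @param augment apply a random dihedral transform (flip and 90-degree
#'   rotation) to each sample draw — the standard augmentation for
#'   segmentation of orientation-free structures. Draws come from the
#'   same seeded stream, so training stays reproducible.
#' @param verbose print per-epoch losses.
#' @return an [anet_init()]-shaped model with an added `log` data frame
#'   (epoch, loss, val_loss) and `best_epoch`.
#' @export
anet_train <- function(pairs, config, train_cfg = train_config(),
                       val = NULL, w0 = 10, sigma_w = 5,
                       augment = TRUE, verbose = FALSE) {
  if (!length(pairs)) stop("empty dataset")
  norm_x <- function(x) {
    if (inherits(x, "intensity_image")) x$pixels / (2^x$bit_depth - 1)
    else x
  }
  xs <- lapply(pairs, function(p) norm_x(p$x))
  wms <- lapply(pairs, function(p)
    compute_weight_map(p$g, w0 = w0, sigma = sigma_w))
  val_xs <- lapply(val, function(p) norm_x(p$x))
  val_wms <- lapply(val, function(p)
    compute_weight_map(p$g, w0 = w0, sigma = sigma_w))
  with_seed(train_cfg$seed, {
    model <- anet_init(config, seed = NULL)
    if (train_cfg$epochs == 0L) {
      model$log <- data.frame(epoch = integer(), loss = numeric(),
                              val_loss = numeric())
      model$best_epoch <- NA_integer_
      return(model)
    }
    opt <- adam_new(model$params)
    n <- length(pairs)
    log <- data.frame(epoch = seq_len(train_cfg$epochs), loss = NA_real_,
                      val_loss = NA_real_)
    best <- list(loss = Inf, params = NULL, stats = NULL,
                 epoch = NA_integer_)
    npix <- vapply(xs, length, numeric(1))
    for (ep in seq_len(train_cfg$epochs)) {
      stage <- floor(3 * (ep - 1) / train_cfg$epochs)
      lr_ep <- train_cfg$lr * train_cfg$lr_decay^stage
      ord <- sample.int(n)
      tot <- 0
      for (i in ord) {
        xi <- xs[[i]]; wmi <- wms[[i]]
        if (augment) {
          op <- sample.int(8L, 1L) - 1L
          xi <- dihedral(xi, op)
          wmi <- list(omega = dihedral(wmi$omega, op),
                      g = dihedral(wmi$g, op))
        }
        fw <- anet_forward_full(model, xi, train = TRUE)
        E <- weighted_cross_entropy(fw$P, wmi)
        if (!is.finite(E))
          stop("non-finite loss at epoch ", ep, ", pair ", i,
               "; try a smaller learning rate")
        tot <- tot + E
        grads <- anet_backward(model, fw, ce_activation_grad(fw$P, wmi))
        st <- adam_step(model$params, grads, opt, lr = lr_ep)
        model$params <- st$params
        opt <- st$state
      }
      log$loss[ep] <- tot / sum(npix)
      mon <- log$loss[ep]
      if (length(val)) {
        vtot <- 0
        for (j in seq_along(val)) {
          Pv <- anet_forward(model, val_xs[[j]], train = FALSE)
          vtot <- vtot + weighted_cross_entropy(Pv, val_wms[[j]])
        }
        log$val_loss[ep] <- vtot / sum(vapply(val_xs, length, numeric(1)))
        mon <- log$val_loss[ep]
      }
      if (mon < best$loss) {
        best <- list(loss = mon, params = model$params,
                     stats = snapshot_stats(model$stats), epoch = ep)
      }
      if (verbose)
        message(sprintf("epoch %d  loss %.5f%s", ep, log$loss[ep],
                        if (length(val))
                          sprintf("  val %.5f", log$val_loss[ep]) else ""))
    }
    model$params <- best$params
    model$stats <- restore_stats(best$stats)
    model$log <- log
    model$best_epoch <- best$epoch
    model
  })
}

#' Foreground probability of a tile
#'
#' Inference-mode forward pass returning the probability of the
#' filament class at every pixel.
#'
#' @param model a trained [anet_model].
#' @param x input tile (matrix in `[0, 1]` or [intensity_image]).
#' @return `[H, W]` matrix of foreground probabilities.
#' @export
anet_predict <- function(model, x) {
  P <- anet_forward(model, x, train = FALSE)
  P[, , dim(P)[3L]]
}
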