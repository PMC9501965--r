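# 2D linear convolution helpers. Zero-padded FFT convolution with
# "same"-size output, plus a symmetric (mirror) padded variant used where
# edge ringing matters (Richardson-Lucy, SSIM windows). Kernels must
# have odd sides so the centre is unambiguous.

conv2_same <- function(x, k) {
  kd <- dim(k)
  if (any(kd %% 2L == 0L)) stop("kernel sides must be odd")
  xd <- dim(x)
  fd <- xd + kd - 1L
  # pad both operands to the full-convolution size
  xp <- matrix(0, fd[1L], fd[2L]); xp[seq_len(xd[1L]), seq_len(xd[2L])] <- x
  kp <- matrix(0, fd[1L], fd[2L]); kp[seq_len(kd[1L]), seq_len(kd[2L])] <- k
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    prod(fd)
  off <- (kd - 1L) %/% 2L
  full[off[1L] + seq_len(xd[1L]), off[2L] + seq_len(xd[2L]), drop = FALSE]
}

# mirror-pad by (p1, p2) on each side (edge-inclusive symmetric extension)
pad_symmetric <- function(x, p1, p2 = p1) {
  n1 <- nrow(x); n2 <- ncol(x)
  ri <- c(rev(seq_len(min(p1, n1))), seq_len(n1),
          n1 + 1L - seq_len(min(p1, n1)))
  ci <- c(rev(seq_len(min(p2, n2))), seq_len(n2),
          n2 + 1L - seq_len(min(p2, n2)))
  x[ri, ci, drop = FALSE]
}

conv2_reflect <- function(x, k) {
  p <- (dim(k) - 1L) %/% 2L
  xp <- pad_symmetric(x, p[1L], p[2L])
  out <- conv2_same(xp, k)
  out[p[1L] + seq_len(nrow(x)), p[2L] + seq_len(ncol(x)), drop = FALSE]
}
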