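# Independent scalar oracles used to pin down the vectorized paths.
# Everything here is deliberately naive: explicit loops, no shared code
# with the implementation.

# all valid top-left positions of a kernel slid over an H x W grid
oracle_patch_positions <- function(H, W, kh, kw, stride) {
  pos <- list()
  for (r in seq(1, H, by = stride)) {
    for (cc in seq(1, W, by = stride)) {
      if (r + kh - 1 <= H && cc + kw - 1 <= W)
        pos[[length(pos) + 1L]] <- c(r, cc)
    }
  }
  pos
}

# scalar-by-scalar attention: q, k, v are C x P x B arrays
oracle_attention <- function(q, k, v) {
  C <- dim(q)[1]; P <- dim(q)[2]; B <- dim(q)[3]
  A <- array(0, c(C, C, B))
  out <- array(0, c(C, P, B))
  for (b in 1:B) {
    for (i in 1:C) {
      sc <- numeric(C)
      for (j in 1:C) {
        s <- 0
        for (p in 1:P) s <- s + (1 / (1 + exp(-q[i, p, b]))) * k[j, p, b]
        sc[j] <- s
      }
      e <- exp(sc - max(sc))
      A[i, , b] <- e / sum(e)
    }
    for (i in 1:C) for (p in 1:P) {
      s <- 0
      for (j in 1:C) s <- s + A[i, j, b] * v[j, p, b]
      out[i, p, b] <- s
    }
  }
  list(A = A, out = out)
}

# overlap-mean fold by explicit scatter-and-divide accumulation
oracle_fold <- function(patches, H, W, kh, kw, stride) {
  C <- dim(patches)[1]
  acc <- array(0, c(C, H, W))
  cnt <- matrix(0, H, W)
  b <- 0L
  for (r in seq(1, H - kh + 1, by = stride)) {
    for (cc in seq(1, W - kw + 1, by = stride)) {
      b <- b + 1L
      p <- 0L
      for (dr in 0:(kh - 1)) for (dc in 0:(kw - 1)) {
        p <- p + 1L
        acc[, r + dr, cc + dc] <- acc[, r + dr, cc + dc] + patches[, p, b]
        cnt[r + dr, cc + dc] <- cnt[r + dr, cc + dc] + 1 / C
      }
    }
  }
  cnt <- cnt * C        # one pass per channel added 1/C each
  for (ci in 1:C) acc[ci, , ] <- acc[ci, , ] / pmax(1, cnt)
  acc
}

# magnitude spectrum of one Hann-windowed segment by direct DFT
oracle_segment_dft <- function(seg) {
  n <- length(seg)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  x <- seg * w
  freqs <- 0:(n / 2 - 1)
  sapply(freqs, function(f) Mod(sum(x * exp(-2i * pi * f * (0:(n - 1)) / n))))
}

# tiny labeled dataset of random spectrogram stacks for classifier tests
toy_dataset <- function(n, C = 2, H = 8, K = 2, seed = 1) {
  set.seed(seed)
  list(x = lapply(seq_len(n), function(i) array(runif(C * H * H), c(C, H, H))),
       y = rep_len(0:(K - 1), n))
}

tiny_config <- function(...) {
  args <- list(...)
  do.call(model_config, utils::modifyList(
    list(spec_size = 8, heads = c(3, 4, 5), hidden = 6, n_classes = 3), args))
}
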