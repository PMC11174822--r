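# Dense (1x1 convolution over the head axis) and pooling layers, each with
# an explicit forward returning a cache and a matching backward.  All head
# convolutions share weights across the sensor-channel axis C, which is what
# makes the trunk channel-count agnostic.
#
# Internally every tensor carries a trailing batch axis: (C, M, H, W, N).
# The batch folds into the "sample-like" axes of each operation (columns of
# the 1x1 convolutions, score slots of the attention, rows of the pooling
# matmuls), so a minibatch costs one set of vectorized calls instead of N.

as_batch5 <- function(x) {
  d <- dim(x)
  if (length(d) == 4L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 5L) stop_ca("expected a C x M x H x W (x N) array")
  x
}

drop_batch <- function(x) {
  d <- dim(x)
  stopifnot(d[5L] == 1L)
  dim(x) <- d[1:4]
  x
}

# ---- parameter initializers -------------------------------------------------

init_expand_params <- function(out_heads) {
  list(w1 = init_uniform(out_heads, 1),
       b1 = numeric(out_heads),
       w2 = init_uniform(c(out_heads, out_heads), out_heads),
       b2 = numeric(out_heads))
}

init_mix_params <- function(in_heads, out_heads) {
  list(w = init_uniform(c(out_heads, in_heads), in_heads),
       b = numeric(out_heads))
}

init_linear_params <- function(n_in, n_out, zero = FALSE) {
  list(w = if (zero) matrix(0, n_out, n_in) else init_uniform(c(n_out, n_in), n_in),
       b = numeric(n_out))
}

# ---- head expansion (first iteration, double-layer 1x1 block) ---------------

#' Expand a single head to M heads (first-iteration dense layer)
#'
#' Double-layer 1x1 convolution over the head axis: the first layer expands
#' the single input head to `out_heads` copies with scalar filters, the
#' second linearly recombines across those heads.  Weights are shared
#' across the sensor channels, so the layer accepts any channel count.
#'
#' @param input numeric array `C x 1 x H x W`.
#' @param params parameter list with `w1`, `b1` (length `out_heads`) and
#'   `w2` (`out_heads x out_heads`), `b2`; see `init_expand_params`.
#' @return numeric array `C x out_heads x H x W`.
#' @export
expand_heads_first <- function(input, params) {
  drop_batch(expand_heads_fwd(as_batch5(input), params)$out)
}

expand_heads_fwd <- function(input, params) {
  d <- dim(input)                              # (C, 1, H, W, N)
  if (d[2L] != 1L)
    stop_ca("first-iteration input must have a single head (got M = ", d[2L], ")")
  xv <- as.vector(input)                       # length C*H*W*N
  y1 <- outer(params$w1, xv) + params$b1       # (M, C*H*W*N)
  ym <- params$w2 %*% y1 + params$b2
  M <- length(params$w1)
  out <- array(ym, c(M, d[1L], d[3L], d[4L], d[5L]))
  out <- aperm(out, c(2L, 1L, 3L, 4L, 5L))
  list(out = out, cache = list(xv = xv, y1 = y1, params = params, dims = d))
}

expand_heads_bwd <- function(cache, dout) {
  d <- cache$dims; M <- nrow(cache$y1)
  dym <- aperm(dout, c(2L, 1L, 3L, 4L, 5L))
  dim(dym) <- c(M, d[1L] * d[3L] * d[4L] * d[5L])
  p <- cache$params
  dw2 <- tcrossprod(dym, cache$y1)
  db2 <- rowSums(dym)
  dy1 <- crossprod(p$w2, dym)
  dw1 <- as.vector(dy1 %*% cache$xv)
  db1 <- rowSums(dy1)
  dxv <- as.vector(crossprod(dy1, p$w1))
  dx <- array(dxv, c(d[1L], 1L, d[3L], d[4L], d[5L]))
  list(dx = dx, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

# ---- head mixing (later iterations, single 1x1xM convolution) ---------------

#' Mix M heads into out_heads by a 1x1 convolution over the head axis
#'
#' Each output head is a learned linear combination of the input heads,
#' applied identically at every sensor channel and spatial position.  With
#' a single output head and uniform weights this is the head average; with
#' several output heads it is the convolution-based multi-head generation
#' used from the second attention iteration onward.
#'
#' @param input numeric array `C x M x H x W`.
#' @param params parameter list with `w` (`out_heads x M`) and `b`
#'   (length `out_heads`); see `init_mix_params`.
#' @return numeric array `C x out_heads x H x W`.
#' @export
mix_heads <- function(input, params) {
  drop_batch(mix_heads_fwd(as_batch5(input), params)$out)
}

mix_heads_fwd <- function(input, params) {
  d <- dim(input)                              # (C, M, H, W, N)
  if (!is.matrix(params$w) || ncol(params$w) != d[2L])
    stop_ca("weight matrix expects ", ncol(params$w), " input heads, got ", d[2L])
  if (nrow(params$w) < 1L) stop_ca("out_heads must be >= 1")
  xm <- aperm(input, c(2L, 1L, 3L, 4L, 5L))
  dim(xm) <- c(d[2L], prod(d[-2L]))
  ym <- params$w %*% xm + params$b
  out <- array(ym, c(nrow(params$w), d[1L], d[3L], d[4L], d[5L]))
  out <- aperm(out, c(2L, 1L, 3L, 4L, 5L))
  list(out = out, cache = list(xm = xm, params = params, dims = d))
}

mix_heads_bwd <- function(cache, dout) {
  d <- cache$dims; O <- nrow(cache$params$w)
  dym <- aperm(dout, c(2L, 1L, 3L, 4L, 5L))
  dim(dym) <- c(O, prod(d[-2L]))
  dw <- tcrossprod(dym, cache$xm)
  db <- rowSums(dym)
  dxm <- crossprod(cache$params$w, dym)
  dim(dxm) <- c(d[2L], d[1L], d[3L], d[4L], d[5L])
  list(dx = aperm(dxm, c(2L, 1L, 3L, 4L, 5L)), grads = list(w = dw, b = db))
}

# ---- standard concat + feed-forward multi-head comparator -------------------

init_std_params <- function(in_heads, out_heads, H, W) {
  n_in <- in_heads * H * W
  list(w = init_uniform(c(out_heads * H * W, n_in), n_in),
       b = numeric(out_heads * H * W))
}

#' Standard concatenation multi-head comparator
#'
#' The conventional multi-head aggregation: per sensor channel, the head
#' maps are concatenated along the feature axis into one long vector and a
#' fully connected map produces features of the same dimensionality as the
#' convolution-based path at that point.  Used only as the ablation
#' comparator for the 1x1-convolution head mixing; its parameter count is
#' larger by a factor of the map area.
#'
#' @param input numeric array `C x M x H x W`.
#' @param params list with `w` (`(O*H*W) x (M*H*W)`) and `b`.
#' @return numeric array `C x O x H x W`.
#' @export
standard_multihead <- function(input, params) {
  drop_batch(standard_multihead_fwd(as_batch5(input), params)$out)
}

standard_multihead_fwd <- function(input, params) {
  d <- dim(input)                              # (C, M, H, W, N)
  n_in <- d[2L] * d[3L] * d[4L]
  if (ncol(params$w) != n_in)
    stop_ca("comparator expects concat length ", ncol(params$w), ", got ", n_in)
  # concat per channel: feature order is head-fastest, then rows, columns
  xm <- aperm(input, c(2L, 3L, 4L, 1L, 5L))
  dim(xm) <- c(n_in, d[1L] * d[5L])
  ym <- params$w %*% xm + params$b             # (O*H*W, C*N)
  O <- nrow(params$w) / (d[3L] * d[4L])
  out <- array(ym, c(O, d[3L], d[4L], d[1L], d[5L]))
  list(out = aperm(out, c(4L, 1L, 2L, 3L, 5L)),
       cache = list(xm = xm, params = params, dims = d, O = O))
}

standard_multihead_bwd <- function(cache, dout) {
  d <- cache$dims
  dym <- aperm(dout, c(2L, 3L, 4L, 1L, 5L))
  dim(dym) <- c(cache$O * d[3L] * d[4L], d[1L] * d[5L])
  dw <- tcrossprod(dym, cache$xm)
  db <- rowSums(dym)
  dxm <- crossprod(cache$params$w, dym)
  dim(dxm) <- c(d[2L], d[3L], d[4L], d[1L], d[5L])
  list(dx = aperm(dxm, c(4L, 1L, 2L, 3L, 5L)), grads = list(w = dw, b = db))
}

#' Parameter count of one head-mixing stage
#'
#' Number of trainable scalars needed to map `in_heads` to `out_heads` on
#' `H x W` maps, for the convolution-based path (`"conv"`; the
#' double-layer first-iteration block when `first = TRUE`) and the
#' standard concat + feed-forward comparator (`"standard"`).  Counts are
#' per projection and computed from the weight-array shapes, so the
#' comparator can be costed even when it is too large to materialize.
#'
#' @param in_heads,out_heads head counts before/after the stage.
#' @param H,W map size at the stage input.
#' @param mode `"conv"` or `"standard"`.
#' @param first logical: first-iteration double-layer block?
#' @return numeric scalar (may exceed integer range).
#' @export
multihead_param_count <- function(in_heads, out_heads, H, W,
                                  mode = c("conv", "standard"),
                                  first = FALSE) {
  mode <- match.arg(mode)
  if (mode == "conv") {
    if (first) {
      (1 * out_heads + out_heads) + (out_heads * out_heads + out_heads)
    } else {
      in_heads * out_heads + out_heads
    }
  } else {
    (in_heads * H * W) * (out_heads * H * W) + out_heads * H * W
  }
}

# ---- adaptive average pooling ----------------------------------------------

# averaging matrix (n_out x n_in) with the usual adaptive regions
# [floor(o*n/N), ceil((o+1)*n/N)); exact block means when divisible
adaptive_avg_matrix <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    s <- floor((o - 1) * n_in / n_out) + 1L
    e <- ceiling(o * n_in / n_out)
    W[o, s:e] <- 1 / (e - s + 1L)
  }
  W
}

#' Adaptive average pooling over the head and spatial axes
#'
#' Pools a `C x M x H x W` tensor to `C x m x h x w` with automatically
#' derived kernels and strides that reach the target exactly (block means
#' when the sizes divide evenly).  With `squeeze_channels = TRUE` the
#' tensor is first permuted to `M x C x H x W` and pooled over
#' `(C, H, W)` to `M x 1 x 1 x 1`, collapsing the sensor channels into a
#' per-head global average; this is the final-iteration squeeze.
#'
#' @param input numeric array `C x M x H x W`.
#' @param pool_target integer vector `c(m, h, w)`; ignored when squeezing.
#' @param squeeze_channels logical flag for the channel-squeeze variant.
#' @return pooled array (`C x m x h x w`, or `M x 1 x 1 x 1` when
#'   squeezing).
#' @export
adaptive_pool <- function(input, pool_target = NULL, squeeze_channels = FALSE) {
  r <- adaptive_pool_fwd(as_batch5(input), pool_target, squeeze_channels)$out
  if (squeeze_channels) array(r, c(nrow(r), 1L, 1L, 1L)) else drop_batch(r)
}

# squeeze output is returned as an (M, N) matrix (per-head feature columns)
adaptive_pool_fwd <- function(input, pool_target = NULL,
                              squeeze_channels = FALSE, mats = NULL) {
  d <- dim(input)                               # (C, M, H, W, N)
  if (squeeze_channels) {
    xp <- aperm(input, c(2L, 5L, 1L, 3L, 4L))
    dim(xp) <- c(d[2L] * d[5L], d[1L] * d[3L] * d[4L])
    out <- matrix(rowMeans(xp), d[2L], d[5L])
    return(list(out = out, cache = list(dims = d, squeeze = TRUE)))
  }
  pool_target <- as.integer(pool_target)
  if (length(pool_target) != 3L) stop_ca("pool_target must be c(m, h, w)")
  if (any(pool_target < 1L)) stop_ca("pool_target dims must be >= 1")
  if (any(pool_target > d[2:4]))
    stop_ca("pool_target (", paste(pool_target, collapse = "x"),
            ") exceeds input dims (", paste(d[2:4], collapse = "x"), ")")
  if (is.null(mats)) {
    mats <- list(
      spatial = kronecker(adaptive_avg_matrix(d[4L], pool_target[3L]),
                          adaptive_avg_matrix(d[3L], pool_target[2L])),
      head = if (pool_target[1L] != d[2L])
        adaptive_avg_matrix(d[2L], pool_target[1L]) else NULL)
  }
  xm <- aperm(input, c(1L, 2L, 5L, 3L, 4L))     # (C, M, N, H, W)
  dim(xm) <- c(d[1L] * d[2L] * d[5L], d[3L] * d[4L])
  ym <- tcrossprod(xm, mats$spatial)            # (C*M*N, h*w)
  hw <- pool_target[2L] * pool_target[3L]
  if (!is.null(mats$head)) {
    y <- array(ym, c(d[1L], d[2L], d[5L] * hw))
    y <- aperm(y, c(2L, 1L, 3L)); dim(y) <- c(d[2L], d[1L] * d[5L] * hw)
    y <- mats$head %*% y
    dim(y) <- c(pool_target[1L], d[1L], d[5L] * hw)
    y <- aperm(y, c(2L, 1L, 3L))
    ym <- y
  }
  out <- array(ym, c(d[1L], pool_target[1L], d[5L], pool_target[2L], pool_target[3L]))
  out <- aperm(out, c(1L, 2L, 4L, 5L, 3L))      # (C, m, h, w, N)
  list(out = out, cache = list(dims = d, squeeze = FALSE, mats = mats,
                               target = pool_target))
}

adaptive_pool_bwd <- function(cache, dout) {
  d <- cache$dims
  if (cache$squeeze) {
    n <- d[1L] * d[3L] * d[4L]
    dxp <- matrix(as.vector(dout) / n, d[2L] * d[5L], n)
    dim(dxp) <- c(d[2L], d[5L], d[1L], d[3L], d[4L])
    return(aperm(dxp, c(3L, 1L, 4L, 5L, 2L)))
  }
  tg <- cache$target; mats <- cache$mats
  hw <- tg[2L] * tg[3L]
  dym <- aperm(dout, c(1L, 2L, 5L, 3L, 4L))     # (C, m, N, h, w)
  dim(dym) <- c(d[1L] * tg[1L] * d[5L], hw)
  if (!is.null(mats$head)) {
    dy <- array(dym, c(d[1L], tg[1L], d[5L] * hw))
    dy <- aperm(dy, c(2L, 1L, 3L)); dim(dy) <- c(tg[1L], d[1L] * d[5L] * hw)
    dy <- crossprod(mats$head, dy)
    dim(dy) <- c(d[2L], d[1L], d[5L] * hw)
    dy <- aperm(dy, c(2L, 1L, 3L))
    dim(dy) <- c(d[1L] * d[2L] * d[5L], hw)
    dym <- dy
  }
  dxm <- dym %*% cache$mats$spatial             # (C*M*N, H*W)
  dim(dxm) <- c(d[1L], d[2L], d[5L], d[3L], d[4L])
  aperm(dxm, c(1L, 2L, 4L, 5L, 3L))
}
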