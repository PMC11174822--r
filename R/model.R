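#' Model configuration
#'
#' Describes the full architecture: spectrogram size, attention kernel and
#' stride, the head schedule of the stacked attention iterations, the
#' classifier, and the ablation switches.
#'
#' The default head schedule is 64/128/256 with the spatial map halved
#' after each of the first two iterations and the final iteration squeezing
#' the sensor channels into a per-head global average, giving a feature
#' vector of length 256.  The default classifier hidden width (2368) is
#' calibrated so that the default 48x48 / 8-class configuration has a
#' 0.83 M parameter budget; see the package vignette for the arithmetic.
#'
#' @param spec_size spectrogram size `c(H, W)` (single number = square).
#' @param kernel attention-kernel size `c(kh, kw)`.
#' @param stride sliding stride; defaults to the kernel side
#'   (non-overlapping patches).
#' @param heads integer vector: output head count of each iteration.
#' @param hidden classifier hidden width.
#' @param n_classes number of target classes (>= 2).
#' @param head_importance logical: include the head-importance gate?
#' @param multihead `"conv"` for 1x1-convolution head mixing (default) or
#'   `"standard"` for the concat + feed-forward comparator.
#' @return a `model_config` list.
#' @examples
#' cfg <- model_config(spec_size = 16, heads = c(8, 16, 32),
#'                     hidden = 64, n_classes = 3)
#' @export
model_config <- function(spec_size = c(48L, 48L), kernel = c(2L, 2L),
                         stride = NULL, heads = c(64L, 128L, 256L),
                         hidden = 2368L, n_classes = 8L,
                         head_importance = TRUE,
                         multihead = c("conv", "standard")) {
  spec_size <- as.integer(rep(spec_size, length.out = 2L))
  kernel <- as.integer(rep(kernel, length.out = 2L))
  stride <- as.integer(stride %||% kernel[1L])
  heads <- as.integer(heads)
  if (length(heads) < 1L || any(heads < 1L))
    stop_ca("head schedule must be non-empty and positive")
  if (any(spec_size < 2L) || any(kernel < 1L) || stride < 1L)
    stop_ca("spec_size, kernel and stride must be positive (spec_size >= 2)")
  if (n_classes < 2L) stop_ca("n_classes must be >= 2")
  if (hidden < 1L) stop_ca("hidden width must be >= 1")
  cfg <- list(spec_size = spec_size, kernel = kernel, stride = stride,
              heads = heads, hidden = as.integer(hidden),
              n_classes = as.integer(n_classes),
              head_importance = isTRUE(head_importance),
              multihead = match.arg(multihead))
  # map sizes entering each iteration: halved after every non-final stage
  sizes <- vector("list", length(heads))
  sz <- spec_size
  for (i in seq_along(heads)) {
    if (any(kernel > sz))
      stop_ca("attention kernel does not fit the iteration-", i,
              " map (", paste(sz, collapse = "x"), ")")
    sizes[[i]] <- sz
    if (i < length(heads)) sz <- pmax(1L, sz %/% 2L)
  }
  cfg$iter_sizes <- sizes
  cfg$feature_dim <- heads[length(heads)]
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("<model_config: %dx%d spectrograms, kernel %dx%d stride %d,\n",
                     "  heads %s, hidden %d, %d classes, gate %s, multihead %s>\n"),
              x$spec_size[1], x$spec_size[2], x$kernel[1], x$kernel[2], x$stride,
              paste(x$heads, collapse = "/"), x$hidden, x$n_classes,
              if (x$head_importance) "on" else "off", x$multihead))
  invisible(x)
}

# static per-iteration geometry (patch indices, fold/pool matrices);
# shared by every forward pass, independent of the channel count
build_static <- function(cfg) {
  n <- length(cfg$heads)
  iters <- vector("list", n)
  for (i in seq_len(n)) {
    sz <- cfg$iter_sizes[[i]]
    idx <- patch_index(sz[1L], sz[2L], cfg$kernel, cfg$stride)
    counts <- tabulate(as.vector(idx), prod(sz))
    bijective <- all(counts <= 1L)
    gmat <- fmat <- NULL
    if (!bijective) {
      # overlapping windows: dense scatter (G) and overlap-mean fold (F)
      gmat <- matrix(0, length(idx), prod(sz))
      gmat[cbind(seq_along(idx), as.vector(idx))] <- 1
      fmat <- sweep(gmat, 2L, pmax(1L, counts), "/")
    }
    last <- i == n
    pool <- NULL
    if (!last) {
      tgt <- cfg$iter_sizes[[i + 1L]]
      pool <- list(
        target = c(cfg$heads[i], tgt),
        mats = list(spatial = kronecker(adaptive_avg_matrix(sz[2L], tgt[2L]),
                                        adaptive_avg_matrix(sz[1L], tgt[1L])),
                    head = NULL))
    }
    iters[[i]] <- list(size = sz, idx = idx, counts = counts,
                       bijective = bijective, gmat = gmat, fmat = fmat,
                       B = ncol(idx), P = nrow(idx), pool = pool, last = last)
  }
  iters
}

init_proj_params <- function(cfg, iter) {
  first <- iter == 1L
  make1 <- function() {
    if (first) {
      init_expand_params(cfg$heads[1L])
    } else if (cfg$multihead == "standard") {
      sz <- cfg$iter_sizes[[iter]]
      init_std_params(cfg$heads[iter - 1L], cfg$heads[iter], sz[1L], sz[2L])
    } else {
      init_mix_params(cfg$heads[iter - 1L], cfg$heads[iter])
    }
  }
  list(q = make1(), k = make1(), v = make1())
}

#' Build a model
#'
#' Assembles the adaptive-convolution trunk (stacked attention
#' iterations), the head-importance gate and the MLP classifier, and
#' initializes all weights (fan-in-scaled uniform, final layer zero,
#' quantized to single precision so checkpoints round-trip exactly).
#' The trunk holds no channel-specific weights, so one built model runs
#' on inputs with any number of sensor channels.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `attn_model`.
#' @export
build_model <- function(cfg, seed = 123L) {
  if (!inherits(cfg, "model_config")) stop_ca("cfg must be a model_config")
  set.seed(as.integer(seed))
  D <- cfg$feature_dim
  params <- list()
  for (i in seq_along(cfg$heads))
    params[[paste0("iter", i)]] <- init_proj_params(cfg, i)
  if (cfg$head_importance)
    params$gate <- init_linear_params(D, D)
  params$fc1 <- init_linear_params(D, cfg$hidden)
  params$fc2 <- init_linear_params(cfg$hidden, cfg$n_classes)
  params <- lapply_leaves(params, quantize_f32)
  structure(list(config = cfg, params = params, static = build_static(cfg)),
            class = "attn_model")
}

lapply_leaves <- function(x, f) {
  if (is.list(x)) lapply(x, lapply_leaves, f = f) else f(x)
}

#' @export
print.attn_model <- function(x, ...) {
  cat(sprintf("<attn_model: %s params (trunk %s)>\n",
              format(count_parameters(x), big.mark = ","),
              format(count_parameters(x, trunk_only = TRUE), big.mark = ",")))
  print(x$config)
  invisible(x)
}

#' Project input heads to query, key and value tensors
#'
#' Three independently parameterized head expansions: the double-layer
#' 1x1 block at the first iteration ([expand_heads_first()]), the
#' single-layer head mixing ([mix_heads()]) afterwards (or the standard
#' comparator in `"standard"` mode).
#'
#' @param input numeric array `C x M x H x W`.
#' @param proj parameter list with elements `q`, `k`, `v` as created by
#'   [build_model()] (`model$params$iter1`, ...).
#' @param first logical: first-iteration double-layer expansion?
#' @param multihead `"conv"` or `"standard"`.
#' @return list with arrays `Q`, `K`, `V`, each `C x out_heads x H x W`.
#' @export
project_qkv <- function(input, proj, first = FALSE, multihead = "conv") {
  f <- if (first) expand_heads_first
       else if (multihead == "standard") standard_multihead
       else mix_heads
  list(Q = f(input, proj$q), K = f(input, proj$k), V = f(input, proj$v))
}

# ---- one attention iteration (batched) --------------------------------------

iteration_fwd <- function(x, proj, st, cfg, iter) {
  first <- iter == 1L
  fwd <- if (first) expand_heads_fwd
         else if (cfg$multihead == "standard") standard_multihead_fwd
         else mix_heads_fwd
  fq <- fwd(x, proj$q); fk <- fwd(x, proj$k); fv <- fwd(x, proj$v)
  d <- dim(fq$out)                       # (C, M, H, W, N)
  C <- d[1L]; M <- d[2L]; N <- d[5L]
  P <- st$P; B <- st$B; HW <- d[3L] * d[4L]
  take <- function(a) {
    dim(a) <- c(C * M, HW, N)
    pa <- a[, as.vector(st$idx), , drop = FALSE]   # (C*M, P*B, N)
    dim(pa) <- c(C, M, P, B, N)
    to_tform5(pa)
  }
  Tq <- take(fq$out); Tk <- take(fk$out); Tv <- take(fv$out)
  at <- attn_forward(Tq, Tk, Tv, P, M * B * N, C)
  att <- from_tform5(at$out, C, M, P, B, N)
  dim(att) <- c(C * M, P * B, N)
  if (st$bijective) {
    fold <- array(0, c(C * M, HW, N))
    fold[, as.vector(st$idx), ] <- att
  } else {
    am <- aperm(att, c(1L, 3L, 2L)); dim(am) <- c(C * M * N, P * B)
    fm <- am %*% st$fmat                   # (C*M*N, HW), overlap means
    dim(fm) <- c(C * M, N, HW)
    fold <- aperm(fm, c(1L, 3L, 2L))
  }
  vprime <- array(fold, c(C, M, d[3L], d[4L], N))
  pf <- if (st$last) {
    adaptive_pool_fwd(vprime, squeeze_channels = TRUE)
  } else {
    adaptive_pool_fwd(vprime, st$pool$target, mats = st$pool$mats)
  }
  list(out = pf$out,
       cache = list(fq = fq$cache, fk = fk$cache, fv = fv$cache,
                    at = at$cache, pool = pf$cache, dims = d,
                    first = first, st = st))
}

iteration_bwd <- function(cache, dout, cfg) {
  st <- cache$st; d <- cache$dims
  C <- d[1L]; M <- d[2L]; N <- d[5L]
  P <- st$P; B <- st$B; HW <- d[3L] * d[4L]
  dvprime <- adaptive_pool_bwd(cache$pool, dout)   # (C, M, H, W, N)
  dim(dvprime) <- c(C * M, HW, N)
  if (st$bijective) {
    datt <- dvprime[, as.vector(st$idx), , drop = FALSE]
  } else {
    dm <- aperm(dvprime, c(1L, 3L, 2L)); dim(dm) <- c(C * M * N, HW)
    da <- tcrossprod(dm, st$fmat)                  # (C*M*N, P*B)
    dim(da) <- c(C * M, N, P * B)
    datt <- aperm(da, c(1L, 3L, 2L))
  }
  dim(datt) <- c(C, M, P, B, N)
  dO <- to_tform5(datt)
  ab <- attn_backward(cache$at, dO)
  scatter <- function(Tg) {
    pa <- from_tform5(Tg, C, M, P, B, N)
    dim(pa) <- c(C * M, P * B, N)
    if (st$bijective) {
      g <- array(0, c(C * M, HW, N))
      g[, as.vector(st$idx), ] <- pa
    } else {
      pm <- aperm(pa, c(1L, 3L, 2L)); dim(pm) <- c(C * M * N, P * B)
      gm <- pm %*% st$gmat                         # scatter-add
      dim(gm) <- c(C * M, N, HW)
      g <- aperm(gm, c(1L, 3L, 2L))
    }
    array(g, d)
  }
  bwd <- if (cache$first) expand_heads_bwd
         else if (cfg$multihead == "standard") standard_multihead_bwd
         else mix_heads_bwd
  bq <- bwd(cache$fq, scatter(ab$dTq))
  bk <- bwd(cache$fk, scatter(ab$dTk))
  bv <- bwd(cache$fv, scatter(ab$dTv))
  list(dx = bq$dx + bk$dx + bv$dx,
       grads = list(q = bq$grads, k = bk$grads, v = bv$grads))
}

#' Run one attention iteration
#'
#' Projects the input to Q/K/V, extracts patches per head, computes
#' cross-channel attention, folds the attended patches back to maps and
#' applies adaptive average pooling (channel squeeze at the final
#' iteration).
#'
#' @param input numeric array `C x M x H x W` (M = 1 at the first
#'   iteration).
#' @param model an `attn_model`.
#' @param iter iteration index (1-based).
#' @return pooled head tensor for the next stage (`M x 1 x 1 x 1` at the
#'   final iteration).
#' @export
run_iteration <- function(input, model, iter) {
  st <- model$static[[iter]]
  d <- dim(input)
  if (length(d) != 4L) stop_ca("input must be C x M x H x W")
  if (!identical(as.integer(d[3:4]), as.integer(st$size)))
    stop_ca("iteration ", iter, " expects ", paste(st$size, collapse = "x"),
            " maps, got ", paste(d[3:4], collapse = "x"))
  out <- iteration_fwd(as_batch5(input), model$params[[paste0("iter", iter)]],
                       st, model$config, iter)$out
  if (st$last) array(out, c(nrow(out), 1L, 1L, 1L)) else drop_batch(out)
}

# ---- gate + classifier ------------------------------------------------------

#' Head-importance gate
#'
#' Flattens the final head tensor to a length-D vector, passes it through
#' a fully connected layer with sigmoid activation, and reweights the
#' vector element-wise by the resulting gates in (0, 1).
#'
#' @param v_mh numeric array or vector flattenable to the gate width.
#' @param params list with `w` (`D x D`) and `b` (length `D`).
#' @return numeric vector of length `D` (gated features).
#' @export
head_importance <- function(v_mh, params) {
  v <- as.vector(v_mh)
  if (length(v) != ncol(params$w))
    stop_ca("gate expects length ", ncol(params$w), ", got ", length(v))
  g <- sigmoid(as.vector(params$w %*% v) + params$b)
  g * v
}

# batched versions: V is a (D, N) matrix of feature columns
gate_fwd <- function(V, params) {
  G <- sigmoid(params$w %*% V + params$b)
  list(out = G * V, cache = list(V = V, G = G, params = params))
}

gate_bwd <- function(cache, dout) {
  V <- cache$V; G <- cache$G
  dZ <- dout * V * G * (1 - G)
  list(dx = dout * G + crossprod(cache$params$w, dZ),
       grads = list(w = tcrossprod(dZ, V), b = rowSums(dZ)))
}

#' Classify a feature vector
#'
#' Two fully connected layers: rectified hidden layer, then softmax over
#' the classes (computed in the log domain).
#'
#' @param v numeric feature vector.
#' @param params list with `fc1` and `fc2` linear parameter lists.
#' @return numeric probability vector summing to 1.
#' @export
classify <- function(v, params) {
  as.vector(clf_fwd(matrix(v, ncol = 1L), params$fc1, params$fc2)$probs)
}

clf_fwd <- function(V, fc1, fc2) {
  Z1 <- fc1$w %*% V + fc1$b
  Hd <- pmax(Z1, 0)
  logits <- fc2$w %*% Hd + fc2$b               # (K, N)
  K <- nrow(logits)
  mx <- logits[1L, ]
  if (K > 1L) for (k in 2:K) mx <- pmax(mx, logits[k, ])
  lz <- mx + log(.colSums(exp(logits - rep(mx, each = K)), K, ncol(logits)))
  logp <- logits - rep(lz, each = K)
  list(probs = exp(logp), logp = logp,
       cache = list(V = V, Hd = Hd, Z1 = Z1, fc1 = fc1, fc2 = fc2))
}

clf_bwd <- function(cache, dlogits) {
  dW2 <- tcrossprod(dlogits, cache$Hd)
  dH <- crossprod(cache$fc2$w, dlogits)
  dH[cache$Z1 <= 0] <- 0
  dW1 <- tcrossprod(dH, cache$V)
  list(dx = crossprod(cache$fc1$w, dH),
       grads = list(fc1 = list(w = dW1, b = rowSums(dH)),
                    fc2 = list(w = dW2, b = rowSums(dlogits))))
}

# ---- full model forward / backward -----------------------------------------

# stacks: list of C x H x W arrays (or one array); returns batched outputs
model_fwd_batch <- function(model, stacks, keep_cache = FALSE) {
  if (!is.list(stacks)) stacks <- list(stacks)
  cfg <- model$config
  d1 <- dim(stacks[[1L]])
  if (length(d1) != 3L) stop_ca("each input must be a C x H x W array")
  if (!identical(as.integer(d1[2:3]), cfg$spec_size))
    stop_ca("model expects ", paste(cfg$spec_size, collapse = "x"),
            " spectrograms, got ", paste(d1[2:3], collapse = "x"))
  N <- length(stacks)
  x <- array(0, c(d1[1L], 1L, d1[2L], d1[3L], N))
  for (s in seq_len(N)) {
    if (!identical(dim(stacks[[s]]), d1))
      stop_ca("all stacks in a batch must share dimensions")
    x[, 1L, , , s] <- stacks[[s]]
  }
  caches <- vector("list", length(cfg$heads))
  for (i in seq_along(cfg$heads)) {
    it <- iteration_fwd(x, model$params[[paste0("iter", i)]],
                        model$static[[i]], cfg, i)
    x <- it$out
    if (keep_cache) caches[[i]] <- it$cache
  }
  vmh <- x                                     # (D, N) after final squeeze
  if (cfg$head_importance) {
    gf <- gate_fwd(vmh, model$params$gate)
    feat <- gf$out
  } else {
    gf <- NULL
    feat <- vmh
  }
  cf <- clf_fwd(feat, model$params$fc1, model$params$fc2)
  list(probs = cf$probs, logp = cf$logp, vmh = vmh, feature = feat,
       cache = if (keep_cache) list(iters = caches, gate = gf$cache,
                                    clf = cf$cache))
}

model_bwd_batch <- function(model, cache, dlogits) {
  cfg <- model$config
  cb <- clf_bwd(cache$clf, dlogits)
  grads <- list(fc1 = cb$grads$fc1, fc2 = cb$grads$fc2)
  dfeat <- cb$dx
  if (cfg$head_importance) {
    gb <- gate_bwd(cache$gate, dfeat)
    grads$gate <- gb$grads
    dvmh <- gb$dx
  } else {
    dvmh <- dfeat
  }
  dx <- dvmh                                   # (D, N), consumed by squeeze bwd
  for (i in rev(seq_along(cfg$heads))) {
    ib <- iteration_bwd(cache$iters[[i]], dx, cfg)
    grads[[paste0("iter", i)]] <- ib$grads
    dx <- ib$dx
  }
  grads
}

# single-sample convenience used by public predictors and tests
model_fwd <- function(model, S, keep_cache = FALSE) {
  if (inherits(S, "spec_stack")) S <- unclass(S)
  fw <- model_fwd_batch(model, list(S), keep_cache)
  list(probs = as.vector(fw$probs), logp = as.vector(fw$logp),
       vmh = as.vector(fw$vmh), feature = as.vector(fw$feature),
       cache = fw$cache)
}

model_bwd <- function(model, cache, dlogits) {
  model_bwd_batch(model, cache, matrix(dlogits, ncol = 1L))
}

#' Forward pass over one spectrogram stack
#'
#' @param model an `attn_model`.
#' @param stack a `spec_stack` or plain `C x H x W` array.
#' @return list with `probs` (class probabilities), `vmh` (flattened
#'   feature vector entering the head-importance gate) and `feature`
#'   (gated features entering the classifier).
#' @export
predict_window <- function(model, stack) {
  fw <- model_fwd(model, stack)
  fw[c("probs", "vmh", "feature")]
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars by enumerating every weight array of
#' the built model.  The trunk (everything except the final
#' classification layer) has a parameter count independent of the number
#' of input channels and of the signal length.
#'
#' @param model an `attn_model`.
#' @param trunk_only logical: exclude the final classification layer?
#' @return integer scalar.
#' @export
count_parameters <- function(model, trunk_only = FALSE) {
  p <- model$params
  if (trunk_only) p$fc2 <- NULL
  count_scalars(p)
}
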