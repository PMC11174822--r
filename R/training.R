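# Seeded training, evaluation and last-layer-replacement fine-tuning.
# Optimization is adaptive-moment estimation (Adam) on the hand-written
# reverse-mode gradients of the full model; the loss is cross-entropy
# computed in the log domain.

#' Training configuration
#'
#' @param lr learning rate (1e-3 for training from scratch; fine-tuning
#'   uses 1e-4, see [fine_tune()]).
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling the split, shuffling and any
#'   weight initialization inside [train_model()].
#' @param val_fraction held-out fraction for the stratified validation
#'   split (0 disables validation).
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer.
#' @param verbose print one structured log line per epoch?
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, epochs = 100L, batch_size = 128L,
                         seed = 123L, val_fraction = 0.2,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         verbose = FALSE) {
  if (lr <= 0 || epochs < 1L || batch_size < 1L)
    stop_ca("lr, epochs and batch_size must be positive")
  if (val_fraction < 0 || val_fraction >= 1)
    stop_ca("val_fraction must be in [0, 1)")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 val_fraction = val_fraction, beta1 = beta1, beta2 = beta2,
                 eps = eps, verbose = isTRUE(verbose)),
            class = "train_config")
}

# dataset: list(x = list of C x H x W stacks, y = integer labels 0-based)
check_dataset <- function(data, n_classes = NULL) {
  if (!is.list(data) || is.null(data$x) || is.null(data$y))
    stop_ca("dataset must be a list with elements x (stacks) and y (labels)")
  if (length(data$x) == 0L) stop_ca("dataset is empty")
  if (length(data$x) != length(data$y))
    stop_ca("x and y lengths differ")
  y <- as.integer(data$y)
  if (any(is.na(y)) || any(y < 0L))
    stop_ca("labels must be non-negative integers")
  if (!is.null(n_classes) && any(y >= n_classes))
    stop_ca("label out of range: labels must lie in [0, ", n_classes, ")")
  y
}

#' Convert labeled windows to a training dataset
#'
#' @param windows list of labeled [mc_window] objects.
#' @param target_size spectrogram size passed to [convert_batch()].
#' @param stft_params optional STFT parameters.
#' @return list with `x` (spectrogram stacks) and `y` (integer labels).
#' @export
windows_to_dataset <- function(windows, target_size = c(48L, 48L),
                               stft_params = NULL) {
  labs <- vapply(windows, function(w) w$label %||% NA_integer_, integer(1))
  if (any(is.na(labs))) stop_ca("all windows must carry labels")
  list(x = convert_batch(windows, target_size, stft_params), y = labs)
}

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  flat <- flatten_params(params)
  gflat <- flatten_params(grads)
  state$t <- state$t + 1L
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  for (nm in names(flat)) {
    g <- gflat[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      cfg$lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + cfg$eps)
  }
  list(params = unflatten_params(flat, params), state = state)
}

# mean loss/accuracy (and mean-loss gradients) over a set of indices,
# processed as one vectorized batch
batch_pass <- function(model, data, idx, with_grads = TRUE, chunk = 256L) {
  if (!with_grads && length(idx) > chunk) {   # bounded memory for evaluation
    parts <- split(idx, ceiling(seq_along(idx) / chunk))
    acc <- loss <- 0
    for (p in parts) {
      bp <- batch_pass(model, data, p, with_grads = FALSE)
      loss <- loss + bp$loss * length(p); acc <- acc + bp$acc * length(p)
    }
    return(list(loss = loss / length(idx), acc = acc / length(idx)))
  }
  n <- length(idx)
  stacks <- lapply(data$x[idx], unclass)
  fw <- model_fwd_batch(model, stacks, keep_cache = with_grads)
  yi <- data$y[idx] + 1L
  pick <- cbind(yi, seq_len(n))
  loss <- -mean(fw$logp[pick])
  pred <- apply(fw$probs, 2L, which.max)     # deterministic argmax
  out <- list(loss = loss, acc = mean(pred == yi))
  if (with_grads) {
    dlogits <- fw$probs
    dlogits[pick] <- dlogits[pick] - 1
    out$grads <- model_bwd_batch(model, fw$cache, dlogits / n)
  }
  out
}

#' Train a model
#'
#' Minimizes cross-entropy with Adam over seeded minibatches.  The
#' dataset is split into stratified train/validation parts, and one row
#' of history per epoch and split records loss and accuracy.  Fully
#' deterministic for a fixed seed.
#'
#' @param model an `attn_model` from [build_model()].
#' @param data list with `x` (list of `C x H x W` spectrogram stacks) and
#'   `y` (integer labels in `[0, n_classes)`), e.g. from
#'   [windows_to_dataset()].
#' @param cfg a [train_config()].
#' @return list with `model` (trained) and `history` (data.frame with
#'   columns epoch, split, loss, accuracy).
#' @export
train_model <- function(model, data, cfg = train_config()) {
  if (!inherits(model, "attn_model")) stop_ca("model must be an attn_model")
  y <- check_dataset(data, model$config$n_classes)
  data$y <- y
  set.seed(cfg$seed)
  n <- length(data$x)
  # stratified validation split
  val_idx <- integer(0)
  if (cfg$val_fraction > 0) {
    for (k in sort(unique(y))) {
      ik <- which(y == k)
      nv <- floor(length(ik) * cfg$val_fraction)
      if (nv > 0) val_idx <- c(val_idx, sample(ik, nv))
    }
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0L) stop_ca("no training samples after split")
  state <- adam_init(model$params)
  hist <- list()
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(train_idx)
    ep_loss <- 0; ep_acc <- 0; nb <- 0L
    for (b0 in seq(1L, length(perm), by = cfg$batch_size)) {
      bidx <- perm[b0:min(b0 + cfg$batch_size - 1L, length(perm))]
      bp <- batch_pass(model, data, bidx)
      upd <- adam_step(model$params, bp$grads, state, cfg)
      model$params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bp$loss; ep_acc <- ep_acc + bp$acc; nb <- nb + 1L
    }
    hist[[length(hist) + 1L]] <-
      data.frame(epoch = ep, split = "train",
                 loss = ep_loss / nb, accuracy = ep_acc / nb)
    if (length(val_idx) > 0L) {
      vp <- batch_pass(model, data, val_idx, with_grads = FALSE)
      hist[[length(hist) + 1L]] <-
        data.frame(epoch = ep, split = "val", loss = vp$loss, accuracy = vp$acc)
      if (cfg$verbose)
        message(sprintf("epoch=%d train_loss=%.4f train_acc=%.3f val_loss=%.4f val_acc=%.3f",
                        ep, ep_loss / nb, ep_acc / nb, vp$loss, vp$acc))
    } else if (cfg$verbose) {
      message(sprintf("epoch=%d train_loss=%.4f train_acc=%.3f",
                      ep, ep_loss / nb, ep_acc / nb))
    }
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Fine-tune a pretrained trunk on a new task
#'
#' Replaces and reinitializes only the final classification layer of the
#' pretrained model, then optimizes all weights at the fine-tuning
#' learning rate (default 1e-4).  Before the first step every non-final
#' weight equals the checkpoint exactly.  Because the trunk is
#' channel-count agnostic, the new dataset may have a different number of
#' sensor channels.
#'
#' @param trunk an `attn_model` or a checkpoint path.
#' @param data new-task dataset (as in [train_model()]).
#' @param n_classes class count of the new task.
#' @param cfg a [train_config()]; the default here uses `lr = 1e-4`.
#' @return list with `model` and `history` as in [train_model()].
#' @export
fine_tune <- function(trunk, data, n_classes,
                      cfg = train_config(lr = 1e-4)) {
  if (is.character(trunk)) {
    model <- load_trunk(trunk, n_classes)
  } else if (inherits(trunk, "attn_model")) {
    tmp <- tempfile(fileext = ".ckpt")
    on.exit(unlink(tmp))
    save_checkpoint(trunk, tmp)
    model <- load_trunk(tmp, n_classes)
  } else {
    stop_ca("trunk must be an attn_model or a checkpoint path")
  }
  train_model(model, data, cfg)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model an `attn_model`.
#' @param data labeled dataset (as in [train_model()]).
#' @return list with `accuracy`, `per_class` (named accuracy vector) and
#'   `confusion` (true x predicted count matrix).  Deterministic.
#' @export
evaluate_model <- function(model, data) {
  y <- check_dataset(data, model$config$n_classes)
  K <- model$config$n_classes
  pred <- integer(length(y))
  for (b0 in seq(1L, length(y), by = 256L)) {
    bidx <- b0:min(b0 + 255L, length(y))
    fw <- model_fwd_batch(model, lapply(data$x[bidx], unclass))
    pred[bidx] <- apply(fw$probs, 2L, which.max) - 1L
  }
  conf <- matrix(0L, K, K,
                 dimnames = list(true = 0:(K - 1), pred = 0:(K - 1)))
  for (s in seq_along(y)) conf[y[s] + 1L, pred[s] + 1L] <-
    conf[y[s] + 1L, pred[s] + 1L] + 1L
  per_class <- diag(conf) / pmax(1L, rowSums(conf))
  names(per_class) <- rownames(conf)
  list(accuracy = mean(pred == y), per_class = per_class, confusion = conf)
}
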