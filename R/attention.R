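# Cross-channel patch-wise self-attention.
#
# For every patch group b (one sliding-window position, shared by all
# channels) and every head, channel i attends over the channels j:
#   score(i, j, b) = sigmoid(q_i)_b . (k_j)_b        (dot over patch axis)
#   A(i, j, b)     = softmax_j score(i, j, b)
#   out(i, b)      = sum_j A(i, j, b) (v_j)_b
# The sigmoid is applied to the query only and there is no temperature.
#
# Internally patches are held in "T-form": an (S*P) x C matrix with one
# column per channel, where S indexes (head, group, batch-sample) score
# slots and runs fastest, and P is the within-patch axis.  With S fastest,
# scaling a channel column by per-slot attention weights is plain vector
# recycling, and the patch-axis dot product is a single .rowSums call, so
# the only loops are over channel pairs (C is small).

# (C, M, P, B, N) -> ((M*B*N*P), C); score slots S = M*B*N run fastest
to_tform5 <- function(x) {
  d <- dim(x)
  xt <- aperm(x, c(2L, 4L, 5L, 3L, 1L))
  dim(xt) <- c(prod(d[-1L]), d[1L])
  xt
}

from_tform5 <- function(xt, C, M, P, B, N) {
  dim(xt) <- c(M, B, N, P, C)
  aperm(xt, c(5L, 1L, 4L, 2L, 3L))
}

# forward over T-form matrices; S score slots, P patch entries
attn_forward <- function(Tq, Tk, Tv, P, S, C) {
  U <- sigmoid(Tq)
  A <- vector("list", C)                    # A[[i]]: (C, S), rows over j
  for (i in seq_len(C)) {
    sc <- matrix(0, C, S)
    Ui <- U[, i]
    for (j in seq_len(C))
      sc[j, ] <- .rowSums(Ui * Tk[, j], S, P)
    mx <- sc[1L, ]
    if (C > 1L) for (j in 2:C) mx <- pmax(mx, sc[j, ])
    e <- exp(sc - rep(mx, each = C))        # max-subtracted, value-preserving
    A[[i]] <- e / rep(.colSums(e, C, S), each = C)
  }
  O <- matrix(0, S * P, C)
  for (i in seq_len(C)) {
    Ai <- A[[i]]
    acc <- Tv[, 1L] * Ai[1L, ]              # length-S weights recycle over P
    if (C > 1L) for (j in 2:C)
      acc <- acc + Tv[, j] * Ai[j, ]
    O[, i] <- acc
  }
  list(out = O, cache = list(U = U, A = A, Tk = Tk, Tv = Tv,
                             P = P, S = S, C = C))
}

attn_backward <- function(cache, dO) {
  P <- cache$P; S <- cache$S; C <- cache$C
  U <- cache$U; A <- cache$A; Tk <- cache$Tk; Tv <- cache$Tv
  dTv <- matrix(0, S * P, C)
  dTk <- matrix(0, S * P, C)
  dU <- matrix(0, S * P, C)
  for (i in seq_len(C)) {
    dOi <- dO[, i]
    Ai <- A[[i]]
    dA <- matrix(0, C, S)
    for (j in seq_len(C)) {
      dTv[, j] <- dTv[, j] + dOi * Ai[j, ]
      dA[j, ] <- .rowSums(dOi * Tv[, j], S, P)
    }
    ds <- Ai * (dA - rep(.colSums(Ai * dA, C, S), each = C))
    Ui <- U[, i]
    dUi <- dU[, i]
    for (j in seq_len(C)) {
      dsj <- ds[j, ]
      dUi <- dUi + dsj * Tk[, j]
      dTk[, j] <- dTk[, j] + dsj * Ui
    }
    dU[, i] <- dUi
  }
  dTq <- dU * U * (1 - U)
  list(dTq = dTq, dTk = dTk, dTv = dTv)
}

check_patch_pair <- function(a, b, what) {
  if (!inherits(a, "patch_tensor") || !inherits(b, "patch_tensor"))
    stop_ca(what, " expects patch_tensor inputs")
  if (!identical(dim(a$values), dim(b$values)))
    stop_ca(what, ": patch tensors have mismatched shapes (",
            paste(dim(a$values), collapse = "x"), " vs ",
            paste(dim(b$values), collapse = "x"), ")")
}

# single-head (C, P, B) -> ((B*P), C) T-form
to_tform1 <- function(v) {
  xt <- aperm(v, c(3L, 2L, 1L))
  dim(xt) <- c(dim(v)[3L] * dim(v)[2L], dim(v)[1L])
  xt
}

#' Cross-channel attention weights for one head
#'
#' For each patch group, scores every (query channel, key channel) pair by
#' the dot product of the sigmoid-transformed query patch with the key
#' patch, then softmax-normalizes over the key channels.  Computed with
#' max subtraction for numerical stability.
#'
#' @param q_patches,k_patches `patch_tensor` objects of identical shape
#'   `C x Patch_Size x B` (see [extract_patches()]).
#' @return `attention_weights`: numeric array `C x C x B`; entry
#'   `[i, j, b]` is the weight with which query channel `i` attends to key
#'   channel `j` in group `b`.  Every row `[i, , b]` sums to 1.
#' @export
attention_weights <- function(q_patches, k_patches) {
  check_patch_pair(q_patches, k_patches, "attention_weights")
  d <- dim(q_patches$values)                 # (C, P, B)
  C <- d[1L]; P <- d[2L]; B <- d[3L]
  fw <- attn_forward(to_tform1(q_patches$values), to_tform1(k_patches$values),
                     to_tform1(k_patches$values), P, B, C)
  A <- array(0, c(C, C, B))
  for (i in seq_len(C)) A[i, , ] <- fw$cache$A[[i]]
  structure(A, class = "attention_weights")
}

#' Apply attention weights to value patches
#'
#' Aggregates the value patches over key channels: output channel `i`,
#' group `b` is `sum_j A[i, j, b] * v_j` at that group.  Shape is
#' preserved, so the result can be folded back to maps with
#' [fold_patches()].
#'
#' @param weights an `attention_weights` array `C x C x B`.
#' @param v_patches a `patch_tensor` with matching `C` and `B`.
#' @return a `patch_tensor` of the same shape and metadata as `v_patches`.
#' @export
attend <- function(weights, v_patches) {
  if (!inherits(v_patches, "patch_tensor"))
    stop_ca("attend expects a patch_tensor for the values")
  d <- dim(v_patches$values)
  if (!is.array(weights) || length(dim(weights)) != 3L ||
      dim(weights)[1L] != d[1L] || dim(weights)[2L] != d[1L] ||
      dim(weights)[3L] != d[3L])
    stop_ca("weights must be C x C x B matching the value patches")
  C <- d[1L]; P <- d[2L]; B <- d[3L]
  Tv <- to_tform1(v_patches$values)
  O <- matrix(0, B * P, C)
  for (i in seq_len(C)) {
    acc <- Tv[, 1L] * weights[i, 1L, ]
    if (C > 1L) for (j in 2:C) acc <- acc + Tv[, j] * weights[i, j, ]
    O[, i] <- acc
  }
  dim(O) <- c(B, P, C)
  out <- v_patches
  out$values <- aperm(O, c(3L, 2L, 1L))
  out
}
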