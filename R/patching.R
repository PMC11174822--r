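#' Number of sliding-window patch groups
#'
#' Counts the positions of an attention kernel slid over an `H x W`
#' spectrogram with a given stride and no padding:
#' `B = prod(floor((size - (kernel - 1) - 1) / stride + 1))`.
#' Windows that do not fit are dropped.
#'
#' @param spec_size integer vector `c(H, W)`.
#' @param kernel integer vector `c(kh, kw)` (a single number is square).
#' @param stride positive integer step of the sliding operation.
#' @return integer: the total number of patch groups `B`.
#' @examples
#' count_patch_groups(c(48, 48), c(2, 2), 2)  # 576
#' @export
count_patch_groups <- function(spec_size, kernel, stride = kernel[1L]) {
  spec_size <- as.integer(rep(spec_size, length.out = 2L))
  kernel <- as.integer(rep(kernel, length.out = 2L))
  stride <- as.integer(stride)
  if (stride < 1L) stop_ca("stride must be >= 1")
  if (any(kernel < 1L)) stop_ca("kernel dims must be >= 1")
  if (any(kernel > spec_size))
    stop_ca("kernel (", paste(kernel, collapse = "x"),
            ") larger than spectrogram (", paste(spec_size, collapse = "x"), ")")
  prod(floor((spec_size - (kernel - 1L) - 1L) / stride + 1L))
}

# column-major linear indices into an H x W matrix for every patch entry;
# returns a P x B integer matrix.  Group order is row-major over window
# positions (column position fastest); within a patch, entries are
# row-major over the kernel window (column offset fastest).
patch_index <- function(H, W, kernel, stride) {
  kh <- kernel[1L]; kw <- kernel[2L]
  r0 <- seq.int(1L, H - kh + 1L, by = stride)
  c0 <- seq.int(1L, W - kw + 1L, by = stride)
  # row-major entry order within the kernel: dr outer, dc inner
  offs <- as.vector(t(outer(0:(kh - 1L), (0:(kw - 1L)) * H, "+")))
  # row-major group order over positions: r0 outer, c0 inner
  bases <- as.vector(t(outer(r0, (c0 - 1L) * H, "+")))
  idx <- outer(offs, bases, "+")
  storage.mode(idx) <- "integer"
  idx
}

#' Extract sliding patches from channel maps
#'
#' Unfolds `C x H x W` maps into a patch tensor of shape
#' `C x Patch_Size x B`, where `Patch_Size = prod(kernel)` and `B` is
#' given by [count_patch_groups()].  Group order is row-major over window
#' positions and patch entries are row-major flattenings of each kernel
#' window.
#'
#' @param maps numeric array `C x H x W` (one map per channel).
#' @inheritParams count_patch_groups
#' @return an object of class `patch_tensor`: a list with `values`
#'   (`C x Patch_Size x B` array), `kernel`, `stride` and `source_size`.
#' @examples
#' m <- array(1:16, c(1, 4, 4))
#' p <- extract_patches(m, kernel = 2, stride = 2)
#' dim(p$values)  # 1 x 4 x 4
#' @export
extract_patches <- function(maps, kernel, stride = kernel[1L]) {
  if (!is.array(maps) || length(dim(maps)) != 3L)
    stop_ca("maps must be a C x H x W array")
  kernel <- as.integer(rep(kernel, length.out = 2L))
  stride <- as.integer(stride)
  d <- dim(maps)
  B <- count_patch_groups(d[2:3], kernel, stride)   # validates geometry
  idx <- patch_index(d[2L], d[3L], kernel, stride)
  m <- maps; dim(m) <- c(d[1L], d[2L] * d[3L])
  vals <- m[, as.vector(idx), drop = FALSE]
  dim(vals) <- c(d[1L], nrow(idx), B)
  structure(list(values = vals, kernel = kernel, stride = stride,
                 source_size = d[2:3]), class = "patch_tensor")
}

#' Fold a patch tensor back into channel maps
#'
#' Inverse of [extract_patches()].  With `stride = kernel` (non-overlapping
#' windows covering the map) the round trip is exact; with overlapping
#' strides each position receives the mean of all windows covering it.
#' Positions never covered by a window are 0.
#'
#' @param patches a `patch_tensor` as returned by [extract_patches()].
#' @return numeric array `C x H x W`.
#' @export
fold_patches <- function(patches) {
  if (!inherits(patches, "patch_tensor"))
    stop_ca("patches must be a patch_tensor")
  v <- patches$values
  if (!is.array(v) || length(dim(v)) != 3L)
    stop_ca("patch_tensor values must be a C x Patch_Size x B array")
  H <- patches$source_size[1L]; W <- patches$source_size[2L]
  kernel <- patches$kernel; stride <- patches$stride
  if (dim(v)[2L] != prod(kernel))
    stop_ca("patch size ", dim(v)[2L], " does not match kernel ",
            paste(kernel, collapse = "x"))
  B <- count_patch_groups(c(H, W), kernel, stride)
  if (dim(v)[3L] != B)
    stop_ca("patch tensor has ", dim(v)[3L], " groups but geometry implies ", B)
  idx <- patch_index(H, W, kernel, stride)
  C <- dim(v)[1L]
  vm <- v; dim(vm) <- c(C, length(idx))
  out <- matrix(0, C, H * W)
  if (stride >= max(kernel) && length(idx) == length(unique(as.vector(idx)))) {
    out[, as.vector(idx)] <- vm          # bijection: pure rearrangement
  } else {
    counts <- tabulate(as.vector(idx), H * W)
    sums <- rowsum(t(vm), group = as.vector(idx))   # (n_covered, C), sorted
    covered <- sort(unique(as.vector(idx)))
    out[, covered] <- t(sums) / rep(counts[covered], each = C)
  }
  dim(out) <- c(C, H, W)
  out
}
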