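# Binary containers: a JSON header (length-prefixed) followed by packed
# little-endian arrays.  One format for signal datasets ("MCSC1") and one
# for model checkpoints ("ATCK1").  Signals and weights are stored as
# 32-bit floats, labels as 32-bit integers.

write_blob <- function(path, magic, header, arrays, sizes) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(magic), con)
  hj <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  writeBin(length(hj), con, size = 4L, endian = "little")
  writeBin(hj, con)
  for (k in seq_along(arrays)) {
    a <- arrays[[k]]
    if (sizes[k] == 4L && is.double(a))
      writeBin(as.numeric(a), con, size = 4L, endian = "little")
    else
      writeBin(as.integer(a), con, size = 4L, endian = "little")
  }
  invisible(path)
}

read_blob <- function(path, magic) {
  if (!file.exists(path)) stop_ca("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  mg <- rawToChar(readBin(con, "raw", n = nchar(magic)))
  if (!identical(mg, magic))
    stop_ca(path, " is not a valid container (expected magic '", magic, "')")
  hl <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(hl) != 1L || is.na(hl) || hl <= 0L || hl > 1e8)
    stop_ca(path, ": corrupt container header")
  hj <- readBin(con, "raw", n = hl)
  if (length(hj) != hl) stop_ca(path, ": truncated container header")
  header <- jsonlite::fromJSON(rawToChar(hj), simplifyVector = TRUE)
  list(header = header, con_path = path, offset = nchar(magic) + 4L + hl)
}

read_array <- function(con, dims, what = "numeric") {
  n <- prod(dims)
  x <- readBin(con, what, n = n, size = 4L, endian = "little")
  if (length(x) != n) stop_ca("truncated container payload")
  if (length(dims) > 1L) dim(x) <- dims
  x
}

#' Write a signal dataset container
#'
#' Packs labeled multi-channel signal windows into a single binary file:
#' a JSON header (dims, sample rate) followed by the signals as 32-bit
#' floats (`N x C x L`) and the labels as 32-bit integers.
#'
#' @param path output file path.
#' @param windows list of [mc_window] objects sharing `C`, `L` and sample
#'   rate.  Labels are taken from the windows (unlabeled windows get -1).
#' @return `path`, invisibly.
#' @export
write_signal_container <- function(path, windows) {
  if (length(windows) == 0L) stop_ca("no windows to write")
  C <- nrow(windows[[1L]]$samples); L <- ncol(windows[[1L]]$samples)
  sr <- windows[[1L]]$sample_rate
  sig <- array(0, c(C, L, length(windows)))
  labels <- integer(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (!identical(dim(w$samples), c(C, L)) || w$sample_rate != sr)
      stop_ca("all windows must share channel count, length and sample rate")
    sig[, , i] <- w$samples
    labels[i] <- w$label %||% -1L
  }
  header <- list(format = "signal_container", version = 1L,
                 n = length(windows), channels = C, length = L,
                 sample_rate = sr)
  write_blob(path, "MCSC1", header, list(sig, labels), c(4L, 4L))
}

#' Read a signal dataset container
#'
#' @param path file written by [write_signal_container()].
#' @return list of [mc_window] objects (labels attached where present).
#' @export
read_signal_container <- function(path) {
  rb <- read_blob(path, "MCSC1")
  h <- rb$header
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = rb$offset)
  sig <- read_array(con, c(h$channels, h$length, h$n))
  labels <- read_array(con, h$n, "integer")
  lapply(seq_len(h$n), function(i)
    mc_window(matrix(sig[, , i], h$channels, h$length), h$sample_rate,
              label = if (labels[i] >= 0L) labels[i] else NULL))
}

#' Read one signal window from a delimited text file
#'
#' Expects a header row of channel names and one row per time sample, one
#' column per channel (tab, comma or whitespace separated).
#'
#' @param path text file path.
#' @param sample_rate sampling rate in Hz (not stored in the text format).
#' @return an [mc_window] (channel names kept as row names).
#' @export
read_signal_delim <- function(path, sample_rate) {
  if (!file.exists(path)) stop_ca("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- t(as.matrix(df))
  w <- mc_window(m, sample_rate)
  rownames(w$samples) <- colnames(df)
  w
}

# ---- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Single binary container: a JSON block holding the model configuration
#' and the parameter manifest (names and dims), followed by every weight
#' array as 32-bit floats.  Model weights are kept single-precision in
#' memory, so `load_checkpoint(save_checkpoint(m))` reproduces every
#' weight exactly.
#'
#' @param model an `attn_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, "attn_model")) stop_ca("model must be an attn_model")
  flat <- flatten_params(model$params)
  manifest <- lapply(flat, function(p) as.integer(dim(p) %||% length(p)))
  cfg <- model$config
  header <- list(format = "checkpoint", version = 1L,
                 config = list(spec_size = cfg$spec_size, kernel = cfg$kernel,
                               stride = cfg$stride, heads = cfg$heads,
                               hidden = cfg$hidden, n_classes = cfg$n_classes,
                               head_importance = cfg$head_importance,
                               multihead = cfg$multihead),
                 params = manifest)
  write_blob(path, "ATCK1", header, flat, rep(4L, length(flat)))
}

config_from_header <- function(hc) {
  model_config(spec_size = hc$spec_size, kernel = hc$kernel,
               stride = hc$stride, heads = hc$heads, hidden = hc$hidden,
               n_classes = hc$n_classes,
               head_importance = isTRUE(hc$head_importance),
               multihead = hc$multihead)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return an `attn_model` with the stored configuration and weights.
#' @export
load_checkpoint <- function(path) {
  rb <- read_blob(path, "ATCK1")
  h <- rb$header
  if (!identical(h$format, "checkpoint")) stop_ca(path, ": not a checkpoint")
  cfg <- config_from_header(h$config)
  model <- build_model(cfg, seed = 0L)
  flat <- flatten_params(model$params)
  if (!identical(sort(names(flat)), sort(names(h$params))))
    stop_ca(path, ": parameter manifest does not match the stored config")
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", n = rb$offset)
  loaded <- list()
  for (nm in names(h$params))       # manifest order = write order
    loaded[[nm]] <- read_array(con, h$params[[nm]])
  model$params <- unflatten_params(loaded, model$params)
  model
}

#' Load a pretrained trunk into a model with a new class count
#'
#' Rebuilds the stored architecture with `n_classes` output classes,
#' restores every trunk weight (all layers except the final
#' classification layer) from the checkpoint, and reinitializes only the
#' final layer (zeros).  The trunk is channel-count agnostic, so the
#' resulting model can be applied to datasets with a different number of
#' sensor channels without any structural change.
#'
#' @param path checkpoint path.
#' @param n_classes class count of the new task.
#' @return an `attn_model` ready for fine-tuning.
#' @export
load_trunk <- function(path, n_classes) {
  src <- load_checkpoint(path)
  cfg <- src$config
  cfg2 <- model_config(spec_size = cfg$spec_size, kernel = cfg$kernel,
                       stride = cfg$stride, heads = cfg$heads,
                       hidden = cfg$hidden, n_classes = n_classes,
                       head_importance = cfg$head_importance,
                       multihead = cfg$multihead)
  model <- build_model(cfg2, seed = 0L)
  keep <- setdiff(names(model$params), "fc2")
  model$params[keep] <- src$params[keep]
  model$params$fc2 <- list(w = matrix(0, cfg2$n_classes, cfg2$hidden),
                           b = numeric(cfg2$n_classes))
  model
}
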