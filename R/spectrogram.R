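#' Multi-channel signal window
#'
#' A fixed-rate window of raw sensor samples: `C` channels by `L` time
#' points, plus the sampling rate and an optional integer class label.
#'
#' @param samples numeric matrix, channels in rows, time points in columns.
#' @param sample_rate sampling rate in Hz.
#' @param label optional integer class id (0-based).
#' @return an object of class `mc_window`.
#' @examples
#' w <- mc_window(matrix(rnorm(3 * 100), 3), sample_rate = 50)
#' @export
mc_window <- function(samples, sample_rate, label = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_ca("samples must be a numeric matrix (channels x time)")
  if (nrow(samples) < 1L || ncol(samples) < 2L)
    stop_ca("window needs at least 1 channel and 2 time points")
  check_finite(samples, "signal window")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop_ca("sample_rate must be a positive scalar (Hz)")
  if (!is.null(label)) {
    label <- as.integer(label)
    if (is.na(label) || label < 0L) stop_ca("label must be a non-negative integer")
  }
  structure(list(samples = samples, sample_rate = sample_rate, label = label),
            class = "mc_window")
}

#' @export
print.mc_window <- function(x, ...) {
  cat(sprintf("<mc_window: %d channels x %d samples @ %g Hz%s>\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate,
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Default STFT parameters for a window length
#'
#' Segment length is `L/8` rounded to the nearest power of two (minimum
#' 16), with a Hann window and 50% overlap.  For typical wearable-sensor
#' window lengths this yields a raw spectrogram that is roughly square
#' before resizing.
#'
#' @param L signal length in samples.
#' @return list with `n_fft` (segment length) and `hop` (samples between
#'   segment starts).
#' @export
default_stft_params <- function(L) {
  n_fft <- max(16L, as.integer(2^round(log2(L / 8))))
  list(n_fft = n_fft, hop = n_fft %/% 2L)
}

# interpolation weight matrix mapping n_in samples to n_out samples
# (pixel-center aligned linear interpolation, clamped at the borders)
interp_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  if (n_in == 1L) { W[, 1L] <- 1; return(W) }
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- pmin(pmax(src, 1), n_in)
  lo <- pmin(floor(src), n_in - 1L)
  fr <- src - lo
  for (i in seq_len(n_out)) {
    W[i, lo[i]] <- 1 - fr[i]
    W[i, lo[i] + 1L] <- W[i, lo[i] + 1L] + fr[i]
  }
  W
}

# bilinear resize of a matrix to (H, W)
resize_bilinear <- function(mat, H, W) {
  interp_weights(H, nrow(mat)) %*% mat %*% t(interp_weights(W, ncol(mat)))
}

#' Convert a signal window to a normalized log-magnitude spectrogram stack
#'
#' Each channel is transformed with a Hann-windowed short-time Fourier
#' transform, magnitudes are log-scaled (`log(|X| + eps)`), the raw
#' time-frequency image is resized to `target_size` by bilinear
#' interpolation, and each channel is min-max normalized to `[0, 1]`.
#' Row 1 of the result is the lowest frequency band.
#'
#' @param window an [mc_window].
#' @param target_size integer vector `c(H, W)`; a single number is used
#'   for both axes.  Default 48x48.
#' @param stft_params optional list with `n_fft` and `hop`; defaults to
#'   [default_stft_params()] of the window length.
#' @param eps floor added to magnitudes before the log (default 1e-8).
#' @return a `spec_stack`: numeric array `C x H x W` with attributes
#'   `freq_axis` (Hz per row) and `time_axis` (seconds per column).
#' @examples
#' w <- mc_window(matrix(sin(2 * pi * 5 * (0:511) / 100), 1), 100)
#' s <- stft_spectrogram(w, target_size = 16)
#' dim(s)
#' @export
stft_spectrogram <- function(window, target_size = c(48L, 48L),
                             stft_params = NULL, eps = 1e-8) {
  if (!inherits(window, "mc_window")) stop_ca("window must be an mc_window")
  target_size <- as.integer(rep(target_size, length.out = 2L))
  if (any(target_size < 2L)) stop_ca("target_size must be at least 2x2")
  x <- window$samples
  check_finite(x, "signal window")
  C <- nrow(x); L <- ncol(x)
  sp <- stft_params %||% default_stft_params(L)
  n_fft <- as.integer(sp$n_fft); hop <- as.integer(sp$hop %||% (n_fft %/% 2L))
  if (L < n_fft)
    stop_ca("signal length ", L, " is shorter than one STFT segment (", n_fft, ")")
  H <- target_size[1L]; W <- target_size[2L]
  win <- signal::hanning(n_fft)
  out <- array(0, c(C, H, W))
  freq_axis <- time_axis <- NULL
  for (ci in seq_len(C)) {
    sg <- signal::specgram(x[ci, ], n = n_fft, Fs = window$sample_rate,
                           window = win, overlap = n_fft - hop)
    mag <- matrix(Mod(sg$S), nrow = length(sg$f))  # 1-column STFTs drop dims
    lg <- log(mag + eps)                   # freq rows ascending from 0 Hz
    rs <- resize_bilinear(lg, H, W)
    rng <- range(rs)
    out[ci, , ] <- if (diff(rng) > 0) (rs - rng[1L]) / diff(rng) else 0
    if (is.null(freq_axis)) {
      freq_axis <- as.vector(interp_weights(H, length(sg$f)) %*% sg$f)
      time_axis <- as.vector(interp_weights(W, length(sg$t)) %*% as.vector(sg$t))
    }
  }
  structure(out, freq_axis = freq_axis, time_axis = time_axis,
            class = "spec_stack")
}

#' Convert a batch of windows to spectrogram stacks
#'
#' Order-preserving, deterministic map of [stft_spectrogram()] over a list
#' of windows.  All windows must share the channel count and sample rate.
#'
#' @param windows list of [mc_window] objects.
#' @inheritParams stft_spectrogram
#' @return list of `spec_stack` arrays, one per window.
#' @export
convert_batch <- function(windows, target_size = c(48L, 48L),
                          stft_params = NULL) {
  if (length(windows) == 0L) return(list())
  if (!all(vapply(windows, inherits, logical(1), "mc_window")))
    stop_ca("windows must be a list of mc_window objects")
  Cs <- vapply(windows, function(w) nrow(w$samples), integer(1))
  if (length(unique(Cs)) != 1L)
    stop_ca("mixed channel counts in batch: ", paste(unique(Cs), collapse = ", "))
  srs <- vapply(windows, function(w) w$sample_rate, numeric(1))
  if (length(unique(srs)) != 1L)
    stop_ca("mixed sample rates in batch")
  lapply(windows, stft_spectrogram, target_size = target_size,
         stft_params = stft_params)
}
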