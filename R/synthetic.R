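# Seeded generator of labeled multi-channel windows whose classes differ
# in time-frequency content and whose channels are correlated, so the
# cross-channel attention path has structure to exploit.
#
# The trunk reads spectrograms through channel-shared 1x1 convolutions,
# cross-channel patch attention and average pooling, so its features are a
# bag of local cross-channel time-frequency patterns: sensitive to channel
# synchrony and temporal texture, largely insensitive to where in the band
# energy sits.  The default classes therefore differ in carrier layout
# across channels (synchronized vs. spread) and in rhythmicity (steady vs.
# amplitude-modulated bursts), the kind of structure that separates, e.g.,
# rest / walking / tremor in wearable recordings.

#' Synthetic dataset specification
#'
#' Each class is a set of per-channel sinusoidal carriers with random
#' phase and an optional class-specific amplitude-modulation (burst)
#' rate; the phase and the additive white noise are shared across
#' channels to the degree `channel_coupling`, giving cross-channel
#' correlation.  Labels are balanced round-robin.
#'
#' @param n_windows number of windows.
#' @param C channel count.
#' @param L window length in samples.
#' @param sample_rate Hz.
#' @param classes list of class descriptors, each a list with `freqs`
#'   (numeric length `C`, carrier frequency per channel, Hz),
#'   `amplitude`, optional `am_rate` (amplitude-modulation rate in Hz,
#'   0 = steady) and optional `harmonics` (relative amplitudes of integer
#'   multiples of the carrier, default `1` = pure tone).  Defaults:
#'   synchronized pure carriers / spread pure carriers / synchronized
#'   harmonic-rich carriers.
#' @param channel_coupling correlation degree in `[0, 1]` (1 = identical
#'   phase/noise across channels).
#' @param noise_sd white-noise standard deviation.
#' @param am_depth modulation depth for bursting classes (default 0.9).
#' @param seed integer seed.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_windows = 600L, C = 3L, L = 1024L,
                       sample_rate = 100, classes = NULL,
                       channel_coupling = 0.7, noise_sd = 0.25,
                       am_depth = 0.9, seed = 123L) {
  C <- as.integer(C); L <- as.integer(L)
  if (n_windows < 1L) stop_ca("n_windows must be >= 1")
  if (noise_sd < 0) stop_ca("noise_sd must be >= 0")
  if (channel_coupling < 0 || channel_coupling > 1)
    stop_ca("channel_coupling must be in [0, 1]")
  if (is.null(classes)) {
    spread <- seq(6, min(40, 0.8 * sample_rate / 2), length.out = C)
    classes <- list(
      list(freqs = rep(8, C), amplitude = 1),
      list(freqs = spread, amplitude = 1),
      list(freqs = rep(8, C), amplitude = 1, harmonics = c(1, 0.9, 0.8, 0.7)))
  }
  for (cl in classes) {
    if (length(cl$freqs) != C)
      stop_ca("each class needs one carrier frequency per channel")
    hmax <- length(cl$harmonics %||% 1)
    if (any(hmax * cl$freqs >= sample_rate / 2))
      stop_ca("carrier (or harmonic) frequency at or above Nyquist (",
              sample_rate / 2, " Hz)")
    if (any(cl$freqs <= 0)) stop_ca("carrier frequencies must be positive")
  }
  structure(list(n_windows = as.integer(n_windows), C = C, L = L,
                 sample_rate = sample_rate, classes = classes,
                 channel_coupling = channel_coupling, noise_sd = noise_sd,
                 am_depth = am_depth, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate labeled synthetic windows
#'
#' @param spec a [synth_spec()].
#' @return list of labeled [mc_window] objects (class ids `0..K-1`,
#'   assigned round-robin, exactly balanced up to remainder).
#' @export
generate_windows <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop_ca("spec must be a synth_spec")
  set.seed(spec$seed)
  K <- length(spec$classes)
  tt <- (0:(spec$L - 1)) / spec$sample_rate
  rho <- spec$channel_coupling
  out <- vector("list", spec$n_windows)
  for (w in seq_len(spec$n_windows)) {
    k <- ((w - 1L) %% K) + 1L
    cl <- spec$classes[[k]]
    am_rate <- cl$am_rate %||% 0
    phi0 <- stats::runif(1, 0, 2 * pi)          # shared phase process
    e0 <- stats::rnorm(spec$L)                  # shared noise component
    am <- if (am_rate > 0)
      1 + spec$am_depth * sin(2 * pi * am_rate * tt + phi0) else 1
    harm <- cl$harmonics %||% 1
    x <- matrix(0, spec$C, spec$L)
    for (ci in seq_len(spec$C)) {
      phi <- phi0 + (1 - rho) * stats::runif(1, 0, 2 * pi)
      noise <- spec$noise_sd * (sqrt(rho) * e0 +
                                sqrt(1 - rho) * stats::rnorm(spec$L))
      tone <- 0
      for (h in seq_along(harm))            # phase-locked harmonic stack
        tone <- tone + harm[h] * sin(2 * pi * h * cl$freqs[ci] * tt + h * phi)
      x[ci, ] <- cl$amplitude * am * tone + noise
    }
    out[[w]] <- mc_window(x, spec$sample_rate, label = k - 1L)
  }
  out
}

#' Source/target dataset pair for transfer experiments
#'
#' Builds a 4-channel source task and a 3-channel target task with
#' disjoint carrier palettes and different burst rates, mirroring a
#' transfer from a larger sensor deployment to a smaller one with
#' different spectral content.
#'
#' @param seed integer seed (source and target derive distinct streams).
#' @param n_source,n_target dataset sizes.
#' @param noise_sd white-noise level for both tasks.
#' @return list with `source` and `target`, each a list of labeled
#'   [mc_window]s, plus the two `synth_spec`s (`source_spec`,
#'   `target_spec`).
#' @export
make_transfer_pair <- function(seed = 123L, n_source = 600L,
                               n_target = 200L, noise_sd = 0.35) {
  src_classes <- list(list(freqs = rep(12, 4), amplitude = 1),
                      list(freqs = c(5, 18, 30, 44), amplitude = 1),
                      list(freqs = rep(12, 4), amplitude = 1,
                           harmonics = c(1, 0.9, 0.8)))
  tgt_classes <- list(list(freqs = rep(9, 3), amplitude = 1),
                      list(freqs = c(7, 26, 42), amplitude = 1),
                      list(freqs = rep(9, 3), amplitude = 1,
                           harmonics = c(1, 0.9, 0.8, 0.7)))
  src_spec <- synth_spec(n_windows = n_source, C = 4L, classes = src_classes,
                         noise_sd = noise_sd, seed = seed)
  tgt_spec <- synth_spec(n_windows = n_target, C = 3L, classes = tgt_classes,
                         noise_sd = noise_sd, seed = seed + 10007L)
  list(source = generate_windows(src_spec),
       target = generate_windows(tgt_spec),
       source_spec = src_spec, target_spec = tgt_spec)
}
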