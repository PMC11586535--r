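# Log-spectrogram feature extraction.
#
# The recording is cut into half-open Hann-tapered frames starting at sample
# 0 (last partial frame dropped), short-time magnitude spectra are computed,
# restricted to the analysis band, log-compressed with a floor, and
# normalized.  The defaults (50 ms window, 20 ms hop, 20-800 Hz) resolve the
# low-frequency S1/S2 transients from the higher-frequency murmur band.

#' Spectrogram configuration
#'
#' @param window_length Analysis window length in samples.
#' @param hop_length Hop between frame starts in samples; must not exceed
#'   `window_length`.
#' @param fft_size FFT length (zero-padded); must be >= `window_length`.
#' @param frequency_range Two-element Hz interval retained in the output.
#' @param log_floor Small positive constant; magnitudes are clamped to it
#'   before taking logs, bounding the dynamic range from below.
#' @param normalization `"recording"` (z-score over the whole spectrogram,
#'   default; robust to stethoscope gain differences), `"bin"` (z-score per
#'   frequency bin), or `"none"` (raw log magnitudes, for diagnostics).
#' @return A `spectrogram_config` list.
#' @export
spectrogram_config <- function(window_length = 200, hop_length = 80,
                               fft_size = 256,
                               frequency_range = c(20, 800),
                               log_floor = 1e-6,
                               normalization = c("recording", "bin",
                                                 "none")) {
  normalization <- match.arg(normalization)
  if (!(hop_length <= window_length && window_length <= fft_size)) {
    stop("require hop_length <= window_length <= fft_size")
  }
  if (log_floor <= 0) stop("log_floor must be positive")
  structure(list(window_length = as.integer(window_length),
                 hop_length = as.integer(hop_length),
                 fft_size = as.integer(fft_size),
                 frequency_range = frequency_range,
                 log_floor = log_floor, normalization = normalization),
            class = "spectrogram_config")
}

#' Compute a normalized log-spectrogram
#'
#' @param recording A `pcg_recording` (or list with `samples` and
#'   `sample_rate`).
#' @param config A [spectrogram_config()].
#' @return A `pcg_spectrogram`: list with `values` (time x frequency
#'   matrix), `frequencies` (Hz per column), `time_step` (s),
#'   `frequency_step` (Hz).
#' @export
compute_log_spectrogram <- function(recording,
                                    config = spectrogram_config()) {
  x <- recording$samples
  fs <- recording$sample_rate
  w <- config$window_length
  h <- config$hop_length
  if (length(x) < w) stop("recording shorter than one analysis window")
  n_frames <- (length(x) - w) %/% h + 1L
  starts <- (seq_len(n_frames) - 1L) * h
  idx <- outer(seq_len(w), starts, "+")     # w x n_frames
  frames <- matrix(x[idx], nrow = w)
  taper <- as.numeric(signal::hanning(w))
  frames <- frames * taper
  if (config$fft_size > w) {
    frames <- rbind(frames,
                    matrix(0, config$fft_size - w, n_frames))
  }
  spec <- stats::mvfft(frames)
  n_bins <- config$fft_size %/% 2 + 1L
  mag <- Mod(spec[seq_len(n_bins), , drop = FALSE])
  freqs <- (seq_len(n_bins) - 1L) * fs / config$fft_size
  keep <- freqs >= config$frequency_range[1] &
    freqs <= config$frequency_range[2]
  logmag <- t(log(pmax(mag[keep, , drop = FALSE], config$log_floor)))
  vals <- switch(config$normalization,
                 none = logmag,
                 recording = {
                   s <- stats::sd(logmag)
                   if (!is.finite(s) || s < 1e-12) {
                     logmag - mean(logmag)
                   } else {
                     (logmag - mean(logmag)) / s
                   }
                 },
                 bin = {
                   mu <- colMeans(logmag)
                   s <- apply(logmag, 2, stats::sd)
                   s[!is.finite(s) | s < 1e-12] <- 1
                   sweep(sweep(logmag, 2, mu), 2, s, "/")
                 })
  structure(list(values = vals, frequencies = freqs[keep],
                 time_step = h / fs,
                 frequency_step = fs / config$fft_size),
            class = "pcg_spectrogram")
}

# Average-pool adjacent spectrogram frames by an integer factor (trailing
# remainder dropped).  Used to shorten sequences before the recurrent model.
pool_time <- function(values, factor) {
  if (factor <= 1L) return(values)
  n <- nrow(values) %/% factor
  if (n < 1L) stop("time_pool factor larger than the number of frames")
  idx <- rep(seq_len(n), each = factor)
  rowsum(values[seq_len(n * factor), , drop = FALSE], idx) / factor
}
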