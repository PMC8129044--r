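#' Per-millisecond feature track
#'
#' A time series of one acoustic feature on a fixed 1 ms grid: the amplitude
#' envelope (dimensionless, >= 0), the mean frequency (Hz, spectral power
#' centroid) or the Wiener entropy (log10 spectral flatness, <= 0).
#'
#' @param values numeric vector, one value per millisecond.
#' @param kind one of `"amplitude"`, `"frequency"`, `"entropy"`.
#' @param start_ms integer offset of the first value on the song's ms grid.
#' @return An object of class `feature_track`.
#' @export
feature_track <- function(values, kind = c("amplitude", "frequency", "entropy"),
                          start_ms = 0L) {
  kind <- match.arg(kind)
  if (!is.numeric(values) || length(values) == 0L || !all(is.finite(values)))
    ms_input_error("feature_track: values must be non-empty, finite numeric")
  if (kind == "amplitude" && any(values < 0))
    ms_input_error("feature_track: amplitude values must be >= 0")
  if (kind == "entropy" && any(values > 0))
    ms_input_error("feature_track: entropy values must be <= 0")
  if (kind == "frequency" && any(values < 0))
    ms_input_error("feature_track: frequency values must be >= 0")
  structure(list(kind = kind, values = as.numeric(values),
                 start_ms = as.integer(start_ms)),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track[%s]: %d ms from t=%d, range [%.4g, %.4g]>\n",
              x$kind, length(x$values), x$start_ms,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.feature_track <- function(x) length(x$values)

# Frame start indices (1-based, sample units) for a 1 ms analysis grid.
# Frame t (t = 0-based ms) is centred at (t + 0.5) ms; edge frames are
# shifted inward so every frame holds exactly frame_len samples.
ms_frame_starts <- function(n_samples, sample_rate, frame_len) {
  n_ms <- floor(1000 * n_samples / sample_rate)
  centers <- round((seq_len(n_ms) - 0.5) * sample_rate / 1000)
  starts <- centers - frame_len %/% 2L + 1L
  pmax(1L, pmin(as.integer(starts), n_samples - frame_len + 1L))
}

#' Amplitude envelope (un-normalized)
#'
#' RMS amplitude in a sliding window (default 10 ms) stepped at 1 ms.
#'
#' @param clip an [audio_clip()].
#' @param window_ms analysis window length in ms.
#' @return A `feature_track` of kind `"amplitude"`, one value per ms.
#' @export
amplitude_envelope <- function(clip, window_ms = 10) {
  L <- max(1L, round(window_ms * clip$sample_rate / 1000))
  n <- length(clip$samples)
  if (n < L)
    ms_input_error("amplitude_envelope: clip shorter than one analysis window")
  starts <- ms_frame_starts(n, clip$sample_rate, L)
  cs <- c(0, cumsum(clip$samples^2))
  rms <- sqrt((cs[starts + L] - cs[starts]) / L)
  rms[rms < 0] <- 0  # guard fp round-off
  feature_track(rms, "amplitude")
}

#' Normalize an amplitude envelope in long windows
#'
#' Divides the envelope, within consecutive windows (default 4 s) tiled from
#' the start of the track, by that window's maximum, mapping each window into
#' 0..1. This removes slow intensity fluctuation (e.g. the singer changing
#' position) before amplitude distances are computed. All-zero windows stay
#' all-zero; a final partial window is normalized by its own maximum.
#'
#' @param env an amplitude `feature_track` on the 1 ms grid.
#' @param window_s normalization window length in seconds.
#' @return A normalized amplitude `feature_track` with values in 0..1.
#' @export
normalize_envelope <- function(env, window_s = 4) {
  if (!inherits(env, "feature_track") || env$kind != "amplitude")
    ms_input_error("normalize_envelope: expected an amplitude feature_track")
  w <- max(1L, round(window_s * 1000))
  v <- env$values
  win <- (seq_along(v) - 1L) %/% w
  mx <- ave(v, win, FUN = max)
  out <- ifelse(mx > 0, v / mx, 0)
  out <- pmin(out, 1)
  track <- feature_track(out, "amplitude", env$start_ms)
  track
}

# Short-time power spectra for the 1 ms grid: returns a (nfft/2 + 1) x n_ms
# matrix of Hann-windowed periodogram values, computed in chunks.
ms_power_spectra <- function(clip, frame_ms = 10) {
  L <- max(2L, round(frame_ms * clip$sample_rate / 1000))
  n <- length(clip$samples)
  if (n < L)
    ms_input_error("spectral features: clip shorter than one analysis frame")
  starts <- ms_frame_starts(n, clip$sample_rate, L)
  nfft <- 2^ceiling(log2(L))
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  nbins <- nfft %/% 2L + 1L
  n_ms <- length(starts)
  out <- matrix(0, nbins, n_ms)
  chunk <- 8192L
  idx0 <- seq_len(L) - 1L
  for (lo in seq(1L, n_ms, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_ms)
    cols <- lo:hi
    frames <- matrix(clip$samples[outer(idx0, starts[cols], `+`)], nrow = L)
    frames <- frames * hann
    if (nfft > L) frames <- rbind(frames, matrix(0, nfft - L, length(cols)))
    spec <- mvfft(frames)[seq_len(nbins), , drop = FALSE]
    out[, cols] <- Re(spec)^2 + Im(spec)^2
  }
  list(power = out, nfft = nfft, nbins = nbins)
}

#' Wiener entropy contour
#'
#' Log10 spectral flatness per millisecond: the log of the ratio of the
#' geometric to the arithmetic mean of the short-time power spectrum. Zero
#' for a flat (noise-like) spectrum, strongly negative for tone-like sounds.
#' Values are clamped at `floor` (also assigned to frames of digital
#' silence), since sidelobe bins of pure tones underflow and an unbounded
#' log would be dominated by floating-point noise.
#'
#' @param clip an [audio_clip()].
#' @param frame_ms analysis frame length in ms.
#' @param floor lower clamp, in log10 units (default -10).
#' @return A `feature_track` of kind `"entropy"` (values in `[floor, 0]`).
#' @export
wiener_entropy <- function(clip, frame_ms = 10, floor = -10) {
  ps <- ms_power_spectra(clip, frame_ms)
  p <- ps$power
  total <- colSums(p)
  gm_log <- colMeans(log(pmax(p, 1e-300)))
  ent <- (gm_log - log(total / ps$nbins)) / log(10)
  ent[!is.finite(ent) | total <= 0] <- floor
  ent <- pmax(pmin(ent, 0), floor)
  feature_track(ent, "entropy")
}

#' Mean frequency contour
#'
#' Power-weighted spectral centroid per millisecond, in Hz -- a pitch
#' measure locating the center of the distribution of power across
#' frequencies. Frames of digital silence are assigned `silent_fill`
#' (default 0 Hz); after segmentation, frames inside syllables are never
#' silent, so the fill does not enter distances.
#'
#' @param clip an [audio_clip()].
#' @param frame_ms analysis frame length in ms.
#' @param silent_fill value (Hz) assigned to silent frames.
#' @return A `feature_track` of kind `"frequency"` (0..Nyquist).
#' @export
mean_frequency <- function(clip, frame_ms = 10, silent_fill = 0) {
  ps <- ms_power_spectra(clip, frame_ms)
  freqs <- (seq_len(ps$nbins) - 1L) * clip$sample_rate / ps$nfft
  total <- colSums(ps$power)
  cent <- as.numeric(crossprod(ps$power, freqs)) / total
  cent[!is.finite(cent) | total <= 0] <- silent_fill
  feature_track(cent, "frequency")
}

#' All feature tracks of a clip on one time base
#'
#' Computes the normalized amplitude envelope, mean frequency and Wiener
#' entropy contours of a clip. All tracks share the same 1 ms grid and
#' length.
#'
#' @param clip an [audio_clip()].
#' @param window_ms envelope/spectral frame length in ms.
#' @param norm_window_s envelope normalization window in seconds.
#' @param entropy_floor lower clamp for Wiener entropy (log10 units).
#' @return A list with `feature_track` elements `amp` (normalized),
#'   `amp_raw`, `freq`, `ent`.
#' @export
song_features <- function(clip, window_ms = 10, norm_window_s = 4,
                          entropy_floor = -10) {
  amp_raw <- amplitude_envelope(clip, window_ms)
  amp <- normalize_envelope(amp_raw, norm_window_s)
  freq <- mean_frequency(clip, window_ms)
  ent <- wiener_entropy(clip, window_ms, floor = entropy_floor)
  stopifnot(length(amp) == length(freq), length(amp) == length(ent))
  list(amp = amp, amp_raw = amp_raw, freq = freq, ent = ent)
}

#' Write feature tracks to CSV
#'
#' @param features list as returned by [song_features()].
#' @param path output CSV path (columns: time_ms, amplitude, frequency_hz,
#'   wiener_entropy).
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(
    time_ms = features$amp$start_ms + seq_along(features$amp$values) - 1L,
    amplitude = features$amp$values,
    frequency_hz = features$freq$values,
    wiener_entropy = features$ent$values)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
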