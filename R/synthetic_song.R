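# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Parametric syllable template
#'
#' A syllable is modeled as a harmonic stack (fundamental gliding linearly
#' from `f0_start` to `f0_end`, `n_harmonics` partials rolled off by
#' `harmonic_rolloff` dB per partial) mixed with band-limited noise by
#' weight `noisiness`, under an attack/sustain/decay amplitude shape. The
#' model controls the analysis features independently: the amplitude shape
#' sets the envelope, the stack sets the mean frequency, and `noisiness`
#' sets the Wiener entropy.
#'
#' @param duration_ms syllable duration (> 0).
#' @param f0_start,f0_end fundamental frequency at syllable start/end (Hz).
#' @param n_harmonics number of partials (>= 1).
#' @param harmonic_rolloff amplitude decrease per partial (dB).
#' @param noisiness noise mix weight in 0..1 (0 = pure tone, 1 = pure noise).
#' @param attack,decay fractions of the duration used for the linear
#'   amplitude ramp in and out.
#' @param am_depth,am_rate_hz sinusoidal amplitude modulation (depth 0..0.8,
#'   rate in Hz) giving syllables internal envelope structure, from uniform
#'   whistles (depth 0) to pulsed, multi-note-like shapes.
#' @return An object of class `syllable_template`.
#' @export
syllable_template <- function(duration_ms, f0_start, f0_end = f0_start,
                              n_harmonics = 3L, harmonic_rolloff = 6,
                              noisiness = 0.1, attack = 0.15, decay = 0.25,
                              am_depth = 0, am_rate_hz = 0) {
  if (duration_ms <= 0) ms_input_error("syllable_template: duration_ms must be > 0")
  if (f0_start <= 0 || f0_end <= 0)
    ms_input_error("syllable_template: f0 must be > 0")
  if (noisiness < 0 || noisiness > 1)
    ms_input_error("syllable_template: noisiness must be in [0, 1]")
  if (am_depth < 0 || am_depth > 0.8)
    ms_input_error("syllable_template: am_depth must be in [0, 0.8]")
  structure(list(duration_ms = duration_ms, f0_start = f0_start,
                 f0_end = f0_end, n_harmonics = as.integer(n_harmonics),
                 harmonic_rolloff = harmonic_rolloff, noisiness = noisiness,
                 attack = attack, decay = decay, am_depth = am_depth,
                 am_rate_hz = am_rate_hz),
            class = "syllable_template")
}

#' @export
print.syllable_template <- function(x, ...) {
  cat(sprintf(paste0("<syllable_template: %.0f ms, f0 %.0f->%.0f Hz, ",
                     "%d harmonics (-%g dB), noisiness %.2f>\n"),
              x$duration_ms, x$f0_start, x$f0_end, x$n_harmonics,
              x$harmonic_rolloff, x$noisiness))
  invisible(x)
}

#' Draw a random syllable template
#'
#' Parameter ranges follow typical mockingbird syllables: durations
#' 40-250 ms, fundamentals 1-6 kHz with a mild glide, 1-4 partials.
#' Uses the current RNG state.
#'
#' @param durations,f0_range sampling ranges.
#' @return A [syllable_template()].
#' @export
random_template <- function(durations = c(40, 250), f0_range = c(1000, 6000)) {
  f0 <- runif(1, f0_range[1], f0_range[2])
  dur <- runif(1, durations[1], durations[2])
  # onset/offset ramps capped at ~30 ms in absolute time so segmentation
  # boundaries stay sharp on long syllables
  syllable_template(
    duration_ms = dur,
    f0_start = f0,
    f0_end = f0 * runif(1, 0.8, 1.25),
    n_harmonics = sample(1:3, 1),
    harmonic_rolloff = runif(1, 6, 12),
    noisiness = runif(1, 0.01, 0.18),
    attack = runif(1, 0.03, min(0.35, 30 / dur)),
    decay = runif(1, 0.05, min(0.35, 30 / dur)),
    am_depth = runif(1, 0, 0.55),
    am_rate_hz = runif(1, 15, 60))
}

# power centroid of the harmonic stack at the glide midpoint, counting only
# partials that stay below Nyquist
stack_centroid <- function(t, sample_rate) {
  f_mid <- (t$f0_start + t$f0_end) / 2
  k <- seq_len(t$n_harmonics)
  keep <- k * max(t$f0_start, t$f0_end) < sample_rate / 2
  if (!any(keep)) return(min(f_mid, sample_rate / 2 * 0.9))
  k <- k[keep]
  a2 <- 10^(-t$harmonic_rolloff * (k - 1) / 10)
  sum(k * f_mid * a2) / sum(a2)
}

#' Render a syllable template to a waveform
#'
#' Harmonic partials above Nyquist are dropped (count attached as attribute
#' `"dropped_harmonics"`, reported via `message()` when
#' `options(morphsong.verbose = TRUE)`). The noise component is synthesized
#' with a Gaussian spectral bump centred on the harmonic stack's power
#' centroid (sigma = 0.6 x centroid) over a small broadband floor, so that
#' raising `noisiness` raises Wiener entropy while leaving the spectral
#' centroid nearly unchanged. The noise realization uses the current RNG
#' state. Peak amplitude is 0.9.
#'
#' @param t a [syllable_template()].
#' @param sample_rate output rate in Hz.
#' @return Numeric waveform of `round(duration_ms * sample_rate / 1000)`
#'   samples.
#' @export
render_syllable <- function(t, sample_rate) {
  if (t$f0_start >= sample_rate / 2 || t$f0_end >= sample_rate / 2)
    ms_input_error("render_syllable: fundamental at or above Nyquist")
  n <- round(t$duration_ms * sample_rate / 1000)
  if (n < 2L) ms_input_error("render_syllable: duration too short to render")
  f0 <- seq(t$f0_start, t$f0_end, length.out = n)
  phase <- 2 * pi * cumsum(f0) / sample_rate

  k_all <- seq_len(t$n_harmonics)
  keep <- k_all * max(t$f0_start, t$f0_end) < sample_rate / 2
  dropped <- sum(!keep)
  if (dropped > 0L)
    ms_log("render_syllable: dropped ", dropped, " harmonic(s) above Nyquist")

  tone <- numeric(n)
  for (k in k_all[keep])
    tone <- tone + 10^(-t$harmonic_rolloff * (k - 1) / 20) * sin(k * phase)
  tone_rms <- sqrt(mean(tone^2))
  if (tone_rms > 0) tone <- tone / tone_rms

  x <- if (t$noisiness >= 1) {
    ms_shaped_noise(n, sample_rate, stack_centroid(t, sample_rate))
  } else if (t$noisiness <= 0 || !any(keep)) {
    tone
  } else {
    noise <- ms_shaped_noise(n, sample_rate, stack_centroid(t, sample_rate))
    sqrt(1 - t$noisiness) * tone + sqrt(t$noisiness) * noise
  }

  # attack / sustain / decay amplitude shape with optional AM structure
  na <- max(1L, round(t$attack * n))
  nd <- max(1L, round(t$decay * n))
  env <- rep(1, n)
  # square-root ramps: sharp rise/fall at the boundary, gradual inside --
  # keeps detected onsets/offsets within a few ms of the rendered interval
  env[seq_len(na)] <- sqrt(seq(0, 1, length.out = na))
  env[(n - nd + 1L):n] <- pmin(env[(n - nd + 1L):n],
                               sqrt(seq(1, 0, length.out = nd)))
  if (t$am_depth > 0 && t$am_rate_hz > 0) {
    tt <- (seq_len(n) - 1L) / sample_rate
    env <- env * (1 - t$am_depth * (0.5 - 0.5 * cos(2 * pi * t$am_rate_hz * tt)))
  }
  x <- x * env
  peak <- max(abs(x))
  if (peak > 0) x <- 0.9 * x / peak
  attr(x, "dropped_harmonics") <- dropped
  x
}

# band-shaped unit-RMS noise: white noise filtered in the frequency domain
# with profile floor + gaussian bump. The bump is re-centred once so the
# profile's own power centroid lands on `centre` (the broadband floor and
# the asymmetric truncation at 0/Nyquist would otherwise pull it upward),
# keeping timbre changes from leaking into the mean-frequency feature.
ms_shaped_noise <- function(n, sample_rate, centre, sigma_frac = 0.6,
                            floor_rel = 0.15) {
  w <- rnorm(n)
  W <- fft(w)
  nb <- n %/% 2L + 1L
  f <- (0:(nb - 1L)) * sample_rate / n
  sigma <- sigma_frac * centre
  make_prof <- function(cb) floor_rel + exp(-(f - cb)^2 / (2 * sigma^2))
  prof <- make_prof(centre)
  cent0 <- sum(f * prof^2) / sum(prof^2)
  prof <- make_prof(max(150, centre - (cent0 - centre)))
  H <- c(prof, rev(prof[2:(n - nb + 1L)]))[seq_len(n)]
  x <- Re(fft(W * H, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Render a template and measure its feature contours
#'
#' Convenience for tests and the transition simulator: renders the
#' template, extracts the three feature tracks of the resulting clip and
#' returns the whole clip as one [syllable()] (envelope normalized by its
#' own maximum).
#'
#' @param t a [syllable_template()].
#' @param sample_rate rate in Hz.
#' @return A [syllable()].
#' @export
syllable_from_template <- function(t, sample_rate) {
  clip <- audio_clip(render_syllable(t, sample_rate), sample_rate)
  ft <- song_features(clip)
  n <- length(ft$amp)
  syllable(0L, n, ft$amp$values, ft$freq$values, ft$ent$values)
}

#' Morph a syllable template
#'
#' Applies one morphing mode: `pitch` scales the whole f0 glide by
#' `factor`, all else equal; `timbre` shifts `noisiness` by `delta`
#' (direction chosen to stay inside 0..1), duration and f0 contour equal;
#' `stretch` multiplies duration by `factor` (> 1); `squeeze` divides it;
#' `contrast` draws a fresh independent template (current RNG state).
#'
#' @param t a [syllable_template()].
#' @param mode one of [morph_modes()].
#' @param factor pitch or duration factor (mode-dependent).
#' @param delta noisiness change for `timbre`.
#' @param sample_rate used to reject pitch factors pushing the fundamental
#'   to or above Nyquist.
#' @return The morphed [syllable_template()].
#' @export
apply_morph <- function(t, mode, factor = NULL, delta = NULL,
                        sample_rate = 22050) {
  mode <- match.arg(mode, morph_modes())
  switch(mode,
    pitch = {
      if (is.null(factor)) ms_input_error("apply_morph: pitch needs a factor")
      if (max(t$f0_start, t$f0_end) * factor >= sample_rate / 2)
        ms_input_error("apply_morph: pitch factor pushes f0 to/above Nyquist")
      t$f0_start <- t$f0_start * factor
      t$f0_end <- t$f0_end * factor
      t
    },
    timbre = {
      if (is.null(delta)) ms_input_error("apply_morph: timbre needs a delta")
      new <- t$noisiness + delta
      if (new > 1 || new < 0) new <- t$noisiness - delta  # reflect direction
      t$noisiness <- min(1, max(0, new))
      t
    },
    stretch = {
      if (is.null(factor) || factor <= 1)
        ms_input_error("apply_morph: stretch needs factor > 1")
      t$duration_ms <- t$duration_ms * factor
      t$am_rate_hz <- t$am_rate_hz / factor  # true time-stretch: AM slows too
      t
    },
    squeeze = {
      if (is.null(factor) || factor <= 1)
        ms_input_error("apply_morph: squeeze needs factor > 1 (duration is divided)")
      t$duration_ms <- t$duration_ms / factor
      t$am_rate_hz <- t$am_rate_hz * factor
      t
    },
    contrast = random_template())
}

#' Song simulation specification
#'
#' Defines a synthetic song bout: phrases of `reps_range` repetitions of
#' one syllable separated by minibreaths, consecutive phrases linked by a
#' sampled morphing mode (or contrast), additive background white noise.
#' Defaults reflect the structure of mockingbird song: 3-5 repetitions per
#' phrase, 30 ms minibreaths, 400 ms pauses between phrases, 25 dB
#' signal-to-noise.
#'
#' @param n_phrases number of phrases.
#' @param reps_range length-2 integer range of repetitions per phrase
#'   (within 1..20).
#' @param mode_probabilities named numeric over
#'   `timbre, pitch, stretch, squeeze, contrast`, summing to 1.
#' @param pitch_shift range of pitch factors (> 1; direction is randomized).
#' @param duration_factor range of stretch/squeeze factors (> 1).
#' @param noisiness_delta range of timbre noisiness changes.
#' @param minibreath_ms gap between repeated syllables (ms).
#' @param phrase_gap_ms pause between phrases (ms).
#' @param noise_snr_db background white-noise SNR relative to syllable RMS.
#' @param sample_rate audio rate in Hz.
#' @param seed mandatory integer RNG seed.
#' @return An object of class `song_spec`.
#' @export
song_spec <- function(n_phrases = 100L, reps_range = c(3L, 5L),
                      mode_probabilities = c(timbre = 0.2, pitch = 0.2,
                                             stretch = 0.2, squeeze = 0.2,
                                             contrast = 0.2),
                      pitch_shift = c(1.25, 1.5),
                      duration_factor = c(1.5, 2.2),
                      noisiness_delta = c(0.08, 0.2),
                      minibreath_ms = 30L, phrase_gap_ms = 400L,
                      noise_snr_db = 25, sample_rate = 22050L, seed) {
  if (missing(seed)) ms_input_error("song_spec: a seed is required")
  if (n_phrases < 1L) ms_input_error("song_spec: n_phrases must be >= 1")
  if (reps_range[1] < 1L || reps_range[2] > 20L || reps_range[1] > reps_range[2])
    ms_input_error("song_spec: reps_range must lie within 1..20")
  p <- mode_probabilities[morph_modes()]
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    ms_input_error("song_spec: mode_probabilities must cover ",
                   paste(morph_modes(), collapse = "/"),
                   " with non-negative values summing to 1")
  structure(list(n_phrases = as.integer(n_phrases),
                 reps_range = as.integer(reps_range),
                 mode_probabilities = p, pitch_shift = pitch_shift,
                 duration_factor = duration_factor,
                 noisiness_delta = noisiness_delta,
                 minibreath_ms = as.integer(minibreath_ms),
                 phrase_gap_ms = as.integer(phrase_gap_ms),
                 noise_snr_db = noise_snr_db,
                 sample_rate = as.integer(sample_rate),
                 seed = as.integer(seed)),
            class = "song_spec")
}

# sample a morph for the next phrase, keeping chained templates inside
# renderable bounds (duration 25-500 ms, f0 300 Hz - 0.8 Nyquist); the mode
# actually applied is returned alongside the new template
ms_sample_morph <- function(t, spec) {
  mode <- sample(names(spec$mode_probabilities), 1,
                 prob = spec$mode_probabilities)
  sr <- spec$sample_rate
  param <- NA_real_
  if (mode == "pitch") {
    f <- runif(1, spec$pitch_shift[1], spec$pitch_shift[2])
    up_ok <- max(t$f0_start, t$f0_end) * f < 0.8 * sr / 2
    down_ok <- min(t$f0_start, t$f0_end) / f > 300
    f <- if (up_ok && down_ok) { if (runif(1) < 0.5) f else 1 / f }
         else if (up_ok) f else 1 / f
    param <- f
    new <- apply_morph(t, "pitch", factor = f, sample_rate = sr)
  } else if (mode == "timbre") {
    d <- runif(1, spec$noisiness_delta[1], spec$noisiness_delta[2])
    # keep song syllables in the tonal regime the segmentation thresholds
    # assume (Wiener entropy safely below the default -1.0 cutoff): shift
    # towards the side with more headroom, clamped to stay within 0..0.22
    if (t$noisiness < 0.11) d <- min(d, 0.22 - t$noisiness)
    else d <- -min(d, t$noisiness)
    param <- d
    new <- apply_morph(t, "timbre", delta = d)
  } else if (mode %in% c("stretch", "squeeze")) {
    f <- runif(1, spec$duration_factor[1], spec$duration_factor[2])
    if (mode == "stretch" && t$duration_ms * f > 500) mode <- "squeeze"
    if (mode == "squeeze" && t$duration_ms / f < 25) mode <- "stretch"
    if (mode == "stretch" && t$duration_ms * f > 500) f <- 500 / t$duration_ms
    param <- f
    new <- apply_morph(t, mode, factor = f)
  } else {
    new <- apply_morph(t, "contrast")
  }
  list(mode = mode, template = new, param = param)
}

#' Generate a synthetic song with ground truth
#'
#' Phrase 1 uses a random syllable template; each subsequent phrase's
#' template is derived from the previous one by a morphing mode sampled
#' from `spec$mode_probabilities`. Each phrase renders its repetitions
#' (independent noise realizations of the same template) separated by
#' minibreaths; phrases are separated by `phrase_gap_ms`; background white
#' noise is added at `noise_snr_db`. The output is fully determined by
#' `spec$seed`.
#'
#' @param spec a [song_spec()].
#' @return list with `clip` (an [audio_clip()]) and `truth`, itself a list:
#'   `syllables` (data.frame `onset_ms`, `offset_ms`, `phrase`),
#'   `transitions` (data.frame `from_phrase`, `to_phrase`, `mode`,
#'   `param`), `templates` (per-phrase [syllable_template()]s), `spec`.
#' @export
generate_song <- function(spec) generate_song_impl(spec, null_song = FALSE)

#' Generate a null song (independent phrase templates)
#'
#' Identical to [generate_song()] except that every phrase's template is
#' drawn independently -- no morph linkage exists between consecutive
#' phrases, so all transitions are labeled `contrast` in the ground truth.
#' Used as the type-I-error fixture.
#'
#' @param spec a [song_spec()].
#' @return As [generate_song()].
#' @export
generate_null_song <- function(spec) generate_song_impl(spec, null_song = TRUE)

generate_song_impl <- function(spec, null_song) {
  if (!inherits(spec, "song_spec"))
    ms_input_error("generate_song: spec must be a song_spec")
  sr <- spec$sample_rate
  with_seed(spec$seed, {
    templates <- vector("list", spec$n_phrases)
    modes <- character(max(spec$n_phrases - 1L, 0L))
    params <- numeric(length(modes))
    templates[[1L]] <- random_template()
    if (spec$n_phrases > 1L) for (i in 2:spec$n_phrases) {
      if (null_song) {
        templates[[i]] <- random_template()
        modes[i - 1L] <- "contrast"
        params[i - 1L] <- NA_real_
      } else {
        m <- ms_sample_morph(templates[[i - 1L]], spec)
        templates[[i]] <- m$template
        modes[i - 1L] <- m$mode
        params[i - 1L] <- m$param
      }
    }

    reps_vals <- seq(spec$reps_range[1], spec$reps_range[2])
    reps <- reps_vals[sample.int(length(reps_vals), spec$n_phrases,
                                 replace = TRUE)]
    gap_samp <- round(spec$phrase_gap_ms * sr / 1000)
    breath_samp <- round(spec$minibreath_ms * sr / 1000)

    pieces <- list()
    onset <- integer(0); offset <- integer(0); phrase_of <- integer(0)
    cur <- gap_samp  # leading silence
    pieces[[1L]] <- numeric(gap_samp)
    pn <- 1L
    for (i in seq_len(spec$n_phrases)) {
      for (r in seq_len(reps[i])) {
        w <- render_syllable(templates[[i]], sr)
        pn <- pn + 1L; pieces[[pn]] <- as.numeric(w)
        onset <- c(onset, cur); offset <- c(offset, cur + length(w))
        cur <- cur + length(w)
        if (r < reps[i]) {
          pn <- pn + 1L; pieces[[pn]] <- numeric(breath_samp)
          cur <- cur + breath_samp
        }
        phrase_of <- c(phrase_of, i)
      }
      pn <- pn + 1L; pieces[[pn]] <- numeric(gap_samp)  # inter-phrase / trailing
      cur <- cur + gap_samp
    }
    x <- unlist(pieces, use.names = FALSE)

    # additive background noise at the requested SNR vs within-syllable RMS
    sig_mask <- logical(length(x))
    for (s in seq_along(onset)) sig_mask[(onset[s] + 1L):offset[s]] <- TRUE
    sig_rms <- sqrt(mean(x[sig_mask]^2))
    noise_rms <- sig_rms / 10^(spec$noise_snr_db / 20)
    x <- x + rnorm(length(x), sd = noise_rms)
    peak <- max(abs(x))
    if (peak > 1) x <- x / peak

    truth <- list(
      syllables = data.frame(
        onset_ms = as.integer(round(1000 * onset / sr)),
        offset_ms = as.integer(round(1000 * offset / sr)),
        phrase = phrase_of),
      transitions = if (spec$n_phrases > 1L)
        data.frame(from_phrase = seq_len(spec$n_phrases - 1L),
                   to_phrase = 2:spec$n_phrases, mode = modes, param = params)
        else data.frame(from_phrase = integer(0), to_phrase = integer(0),
                        mode = character(0), param = numeric(0)),
      templates = templates,
      spec = spec)
    list(clip = audio_clip(x, sr), truth = truth)
  })
}

#' Write a simulated song to disk
#'
#' Writes the WAV, a ground-truth syllable CSV (onset_ms, offset_ms,
#' phrase), a transitions CSV (from_phrase, to_phrase, mode, param) and a
#' JSON echo of the generating spec.
#'
#' @param song result of [generate_song()] / [generate_null_song()].
#' @param prefix output path prefix (files `<prefix>.wav`,
#'   `<prefix>_syllables.csv`, `<prefix>_transitions.csv`,
#'   `<prefix>_spec.json`).
#' @return character vector of the paths written, invisibly.
#' @export
write_song <- function(song, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- c(wav = paste0(prefix, ".wav"),
             syllables = paste0(prefix, "_syllables.csv"),
             transitions = paste0(prefix, "_transitions.csv"),
             spec = paste0(prefix, "_spec.json"))
  write_wav(song$clip, paths["wav"])
  write.csv(song$truth$syllables, paths["syllables"], row.names = FALSE)
  write.csv(song$truth$transitions, paths["transitions"], row.names = FALSE)
  spec <- unclass(song$truth$spec)
  jsonlite::write_json(spec, paths["spec"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
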