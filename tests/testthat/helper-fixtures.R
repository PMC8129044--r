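# Fixture builders shared across test files. All synthetic, built in code.

sine_clip <- function(freq = 2000, dur_s = 1, sr = 44100, amp = 1) {
  audio_clip(amp * sin(2 * pi * freq * (0:(dur_s * sr - 1)) / sr), sr)
}

noise_clip <- function(dur_s = 1, sr = 44100, amp = 0.3, seed = 1) {
  set.seed(seed)
  audio_clip(amp * pmax(pmin(rnorm(dur_s * sr) / 4, 1), -1), sr)
}

# syllable object straight from hand-specified contours
make_syll <- function(amp, freq = rep(0, length(amp)),
                      ent = rep(0, length(amp)), onset = 0L) {
  syllable(onset, onset + length(amp), amp, freq, ent)
}

# a phrase of n trivial 1-contour syllables (fast, for counting contracts)
toy_phrase <- function(index, n_syll = 1, value = index) {
  syls <- lapply(seq_len(n_syll), function(k)
    make_syll(amp = rep(value / 10, 5), freq = rep(100 * value, 5),
              ent = rep(-value, 5), onset = as.integer(100 * (10 * index + k))))
  phrase(index, syls)
}

toy_song_phrases <- function(n_phrases, n_syll = 1)
  lapply(seq_len(n_phrases), toy_phrase, n_syll = n_syll)

# settings used to segment the simulator's material (documented in the
# methods vignette): the entropy cutoff sits midway between the background
# noise level (~ -0.25) and syllable interiors (<= -1)
SIM_ENT_THRESHOLD <- -0.6

# full pipeline on one simulated song: features -> segments -> phrases
run_sim_pipeline <- function(spec, null_song = FALSE) {
  song <- if (null_song) generate_null_song(spec) else generate_song(spec)
  ft <- song_features(song$clip)
  seg <- segment_syllables(ft$amp, ft$ent, ent_threshold = SIM_ENT_THRESHOLD)
  syls <- extract_syllables(seg, ft$amp, ft$freq, ft$ent)
  list(song = song, features = ft, segments = seg, syllables = syls,
       phrases = group_into_phrases(syls))
}

# strongly separated single-syllable transitions for classifier recovery:
# templates keep every partial below Nyquist across morphs so a pitch shift
# cannot masquerade as a timbre change
mode_fixture_template <- function()
  random_template(durations = c(80, 200), f0_range = c(1000, 2200))

simulate_mode_transitions <- function(n_per_mode = 25, n_calibration = 80,
                                      seed = 123, sr = 22050) {
  set.seed(seed)
  calib <- do.call(rbind, lapply(seq_len(n_calibration), function(i) {
    a <- syllable_from_template(mode_fixture_template(), sr)
    b <- syllable_from_template(mode_fixture_template(), sr)
    d <- syllable_distance(a, b)
    data.frame(amp_dist = d$amp_dist, freq_dist = d$freq_dist,
               ent_dist = d$ent_dist, dur_ratio = d$dur_ratio)
  }))
  th <- calibrate_thresholds(calib)
  modes <- c("pitch", "timbre", "stretch", "squeeze", "contrast")
  rows <- list()
  for (m in modes) for (r in seq_len(n_per_mode)) {
    base <- mode_fixture_template()
    post <- switch(m,
      pitch = {
        f <- runif(1, 1.3, 1.5)
        if (runif(1) < 0.5) f <- 1 / f
        apply_morph(base, "pitch", factor = f, sample_rate = sr)
      },
      timbre = apply_morph(base, "timbre", delta = runif(1, 0.5, 0.65)),
      stretch = apply_morph(base, "stretch", factor = runif(1, 2.4, 3.0)),
      squeeze = apply_morph(base, "squeeze", factor = runif(1, 2.4, 3.0)),
      contrast = mode_fixture_template())
    sa <- syllable_from_template(base, sr)
    sb <- syllable_from_template(post, sr)
    pd <- syllable_distance(sa, sb)
    lab <- classify_transition(pd, c(sa$duration_ms, sb$duration_ms), th)
    rows[[length(rows) + 1L]] <- data.frame(truth = m,
                                            predicted = as.character(lab))
  }
  do.call(rbind, rows)
}
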