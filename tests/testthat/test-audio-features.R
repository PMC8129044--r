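test_that("load_audio round-trips WAV files and averages channels to mono", {
  sr <- 22050
  # silence round-trip
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(numeric(sr), f, sample_rate = sr)
  clip <- load_audio(f)
  expect_equal(duration_ms(clip), 1000)
  expect_true(all(clip$samples == 0))

  # 16-bit quantization round-trip of arbitrary samples
  set.seed(4)
  x <- runif(5000, -0.95, 0.95)
  write_wav(x, f, sample_rate = sr)
  expect_equal(load_audio(f)$samples, x, tolerance = 1e-3)

  # float round-trip is near-exact (32-bit float precision)
  write_wav(x, f, sample_rate = sr, bit_depth = 32L)
  expect_equal(load_audio(f)$samples, x, tolerance = 1e-6)

  # stereo file with identical channels equals the mono read
  g <- withr::local_tempfile(fileext = ".wav")
  write_wav(cbind(x, x), g, sample_rate = sr)
  expect_equal(load_audio(g)$samples, load_audio(f)$samples, tolerance = 1e-3)
})

test_that("unreadable, empty or corrupt audio files raise input errors", {
  expect_error(load_audio(file.path(tempdir(), "no-such-file.wav")),
               class = "morphsong_input_error")
  f <- withr::local_tempfile(fileext = ".wav")
  writeBin(charToRaw("RIFFxxxxWAVE"), f)  # header only, no chunks
  expect_error(load_audio(f), class = "morphsong_input_error")
  writeBin(charToRaw("not a wav at all"), f)
  expect_error(load_audio(f), class = "morphsong_input_error")
})

test_that("amplitude envelope matches RMS closed form and a direct oracle", {
  # interior of a full-scale sine has RMS 1/sqrt(2)
  env <- amplitude_envelope(sine_clip(1000, 1, 44100))
  expect_equal(mean(env$values[100:900]), 1 / sqrt(2), tolerance = 0.02)
  expect_true(all(env$values >= 0))

  # all-zero clip gives an all-zero envelope
  z <- amplitude_envelope(audio_clip(numeric(441), 44100))
  expect_true(all(z$values == 0))

  # hand signal at a toy rate against the independently coded windowed RMS
  sr <- 1000  # 1 sample per ms
  set.seed(11)
  x <- runif(50, -1, 1)
  expect_equal(amplitude_envelope(audio_clip(x, sr))$values,
               direct_rms_envelope(x, sr))

  expect_error(amplitude_envelope(audio_clip(numeric(10), 44100)),
               class = "morphsong_input_error")
})

test_that("envelope normalization maps each 4 s window onto 0..1", {
  const <- feature_track(rep(0.4, 500), "amplitude")
  expect_true(all(normalize_envelope(const)$values == 1))

  # scale invariance within a window
  set.seed(5)
  v <- runif(3000)
  a <- normalize_envelope(feature_track(v, "amplitude"))
  b <- normalize_envelope(feature_track(10 * v, "amplitude"))
  expect_equal(a$values, b$values)

  # two full windows with different maxima both peak at exactly 1
  v2 <- c(runif(4000) * 0.5, runif(4000) * 0.1)
  out <- normalize_envelope(feature_track(v2, "amplitude"))
  expect_equal(max(out$values[1:4000]), 1)
  expect_equal(max(out$values[4001:8000]), 1)
  expect_true(all(out$values >= 0 & out$values <= 1))

  # all-zero window stays all-zero
  v3 <- c(numeric(4000), runif(1000))
  out3 <- normalize_envelope(feature_track(v3, "amplitude"))
  expect_true(all(out3$values[1:4000] == 0))
})

test_that("wiener entropy is 0 for flat spectra, low for tones, high for noise", {
  sr <- 44100
  # an impulse has an analytically flat magnitude spectrum
  x <- numeric(round(0.05 * sr)); x[round(0.025 * sr)] <- 1
  ei <- wiener_entropy(audio_clip(x, sr))
  expect_gt(ei$values[25], -1e-6)
  expect_true(all(ei$values <= 0))

  # pure tone: strongly negative
  et <- wiener_entropy(sine_clip(2000, 0.5, sr))
  expect_lt(mean(et$values[50:450]), -5)

  # white noise: close to flat
  en <- wiener_entropy(noise_clip(0.5, sr))
  expect_gt(mean(en$values), -1)

  # digital silence maps to the floor, never NaN
  es <- wiener_entropy(audio_clip(numeric(sr %/% 10), sr), floor = -10)
  expect_true(all(es$values == -10))
})

test_that("adding noise to a tone raises mean entropy across seeds", {
  sr <- 22050
  tone <- sin(2 * pi * 3000 * (0:(sr %/% 5)) / sr)
  base <- mean(wiener_entropy(audio_clip(tone, sr))$values)
  for (seed in 1:5) {
    set.seed(seed)
    noisy <- tone + rnorm(length(tone), sd = 0.3)
    expect_gt(mean(wiener_entropy(audio_clip(noisy, sr))$values), base)
  }
})

test_that("mean frequency matches spectral-centroid closed forms", {
  sr <- 44100
  mf <- mean_frequency(sine_clip(2000, 0.5, sr))
  expect_equal(mean(mf$values[50:450]), 2000, tolerance = 50 / 2000)

  # equal-power tones at 1 and 3 kHz centre at 2 kHz
  t2 <- sin(2 * pi * 1000 * (0:(sr / 2 - 1)) / sr) +
        sin(2 * pi * 3000 * (0:(sr / 2 - 1)) / sr)
  m2 <- mean_frequency(audio_clip(t2, sr))
  expect_equal(mean(m2$values[50:450]), 2000, tolerance = 0.03)

  # white noise at 44.1 kHz centres near Nyquist/2
  mn <- mean_frequency(noise_clip(0.5, sr))
  expect_equal(mean(mn$values), sr / 4, tolerance = 0.05)
  expect_true(all(mn$values >= 0 & mn$values <= sr / 2))
})

test_that("transposing a harmonic stack raises the centroid frame-wise", {
  sr <- 44100
  stack <- function(f0) {
    tt <- (0:(sr / 4 - 1)) / sr
    sin(2 * pi * f0 * tt) + 0.5 * sin(2 * pi * 2 * f0 * tt) +
      0.25 * sin(2 * pi * 3 * f0 * tt)
  }
  lo <- mean_frequency(audio_clip(stack(1500), sr))
  hi <- mean_frequency(audio_clip(stack(1500 * 1.3), sr))
  interior <- 30:220
  expect_true(all(hi$values[interior] > lo$values[interior]))
})

test_that("all tracks from one clip share a single 1 ms time base", {
  clip <- sine_clip(1500, 0.3, 22050)
  ft <- song_features(clip)
  expect_equal(length(ft$amp), length(ft$freq))
  expect_equal(length(ft$amp), length(ft$ent))
  expect_equal(length(ft$amp), floor(duration_ms(clip)))
  expect_identical(ft$amp$start_ms, ft$ent$start_ms)

  f <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(ft, f)
  df <- read.csv(f)
  expect_named(df, c("time_ms", "amplitude", "frequency_hz", "wiener_entropy"))
  expect_equal(nrow(df), length(ft$amp))
})
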