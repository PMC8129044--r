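test_that("rendered syllables have the right length and spectral character", {
  # 80 ms at 44.1 kHz is exactly 3528 samples
  t <- syllable_template(80, 2000, noisiness = 0)
  expect_length(render_syllable(t, 44100), 3528L)

  # a single constant-f0 harmonic measures ~2 kHz mean frequency
  s <- syllable_from_template(
    syllable_template(150, 2000, n_harmonics = 1L, noisiness = 0), 22050)
  expect_equal(mean(s$freq[30:120]), 2000, tolerance = 0.03)

  # fully noisy syllable: Wiener entropy near 0 (above -1)
  set.seed(20)
  sn <- syllable_from_template(
    syllable_template(150, 2000, n_harmonics = 2L, noisiness = 1), 22050)
  expect_gt(mean(sn$ent[30:120]), -1)

  # peak never exceeds 1
  set.seed(21)
  for (i in 1:5) expect_lte(max(abs(render_syllable(random_template(), 22050))), 1)
})

test_that("harmonics above Nyquist are dropped, not aliased", {
  t <- syllable_template(100, 8000, n_harmonics = 4L, noisiness = 0)
  w <- render_syllable(t, 22050)  # partials 2..4 all above 11.025 kHz
  expect_equal(attr(w, "dropped_harmonics"), 3L)
  s <- syllable_from_template(t, 22050)
  expect_equal(mean(s$freq[30:70]), 8000, tolerance = 0.05)

  expect_error(render_syllable(syllable_template(100, 12000), 22050),
               class = "morphsong_input_error")
})

test_that("apply_morph changes exactly the targeted template field", {
  base <- syllable_template(100, 1000, 1200, noisiness = 0.1)

  st <- apply_morph(base, "stretch", factor = 2)
  expect_equal(st$duration_ms, 200)
  expect_equal(c(st$f0_start, st$f0_end), c(1000, 1200))

  sq <- apply_morph(base, "squeeze", factor = 2)
  expect_equal(sq$duration_ms, 50)

  pt <- apply_morph(base, "pitch", factor = 1.5)
  expect_equal(c(pt$f0_start, pt$f0_end), c(1500, 1800))
  expect_equal(pt$duration_ms, 100)

  tb <- apply_morph(base, "timbre", delta = 0.4)
  expect_equal(tb$noisiness, 0.5)
  expect_equal(tb$duration_ms, 100)
  # reflection keeps noisiness inside 0..1
  tb2 <- apply_morph(syllable_template(100, 1000, noisiness = 0.8),
                     "timbre", delta = 0.4)
  expect_equal(tb2$noisiness, 0.4)

  expect_error(apply_morph(base, "pitch", factor = 20, sample_rate = 22050),
               class = "morphsong_input_error")
  expect_error(apply_morph(base, "stretch", factor = 0.5),
               class = "morphsong_input_error")
})

test_that("morphs are local: untouched features measure unchanged", {
  sr <- 22050
  set.seed(33)
  base <- syllable_template(150, 1400, 1600, n_harmonics = 2L,
                            noisiness = 0.08)
  sa <- syllable_from_template(base, sr)

  # timbre morph at song scale: duration ratio ~1, entropy distance dominates
  tb <- apply_morph(base, "timbre", delta = 0.2)
  sb <- syllable_from_template(tb, sr)
  d <- syllable_distance(sa, sb)
  expect_gte(d$dur_ratio, 0.98)
  # measured frequency contour level conserved within 2% (per-ms centroid
  # jitter rises with noisiness; the underlying f0 trajectory is unchanged)
  expect_lt(abs(mean(sb$freq[20:130]) - mean(sa$freq[20:130])) /
              mean(sa$freq[20:130]), 0.02)
  # entropy moves far more than a mere re-render of the same template
  d0 <- syllable_distance(sa, syllable_from_template(base, sr))
  expect_gt(d$ent_dist, 3 * d0$ent_dist)

  # pitch morph: rendered duration within 2%, frequency clearly shifted
  pt <- apply_morph(base, "pitch", factor = 1.4, sample_rate = sr)
  sp <- syllable_from_template(pt, sr)
  expect_gte(duration_ratio(sa$duration_ms, sp$duration_ms), 0.98)
  expect_gt(mean(sp$freq[30:120]) / mean(sa$freq[30:120]), 1.3)

  # stretch: frequency contour level conserved within 2%
  st <- apply_morph(base, "stretch", factor = 2)
  ss <- syllable_from_template(st, sr)
  expect_equal(mean(ss$freq[50:250]), mean(sa$freq[30:120]), tolerance = 0.02)
  expect_equal(ss$duration_ms / sa$duration_ms, 2, tolerance = 0.02)
})

test_that("generate_song is deterministic and bookkeeping-exact", {
  spec <- song_spec(n_phrases = 6L, seed = 99)
  s1 <- generate_song(spec)
  s2 <- generate_song(spec)
  expect_identical(s1$clip$samples, s2$clip$samples)
  expect_identical(s1$truth$syllables, s2$truth$syllables)
  expect_identical(s1$truth$transitions, s2$truth$transitions)

  # a different seed changes the audio
  expect_false(identical(
    s1$clip$samples, generate_song(song_spec(n_phrases = 6L, seed = 100))$clip$samples))

  # counting: fixed 4 repetitions, 10 phrases -> 40 syllables, 9 transitions
  spec4 <- song_spec(n_phrases = 10L, reps_range = c(4L, 4L), seed = 1)
  g <- generate_song(spec4)
  expect_equal(nrow(g$truth$syllables), 40L)
  expect_equal(nrow(g$truth$transitions), 9L)
  expect_equal(g$truth$transitions$from_phrase, 1:9)
  expect_true(all(g$truth$transitions$mode %in% morph_modes()))

  # intervals sorted, non-overlapping, inside the clip
  syl <- g$truth$syllables
  expect_true(all(diff(syl$onset_ms) > 0))
  expect_true(all(syl$offset_ms[-nrow(syl)] <= syl$onset_ms[-1]))
  expect_lte(max(syl$offset_ms), duration_ms(g$clip))

  # rendered interval lengths match the phrase templates' durations
  durs <- syl$offset_ms - syl$onset_ms
  expected <- vapply(g$truth$templates[syl$phrase], `[[`, numeric(1),
                     "duration_ms")
  expect_equal(durs, expected, tolerance = 0.03)
})

test_that("null songs have independent templates, all transitions contrast", {
  spec <- song_spec(n_phrases = 8L, seed = 17)
  n1 <- generate_null_song(spec)
  n2 <- generate_null_song(spec)
  expect_identical(n1$clip$samples, n2$clip$samples)
  expect_true(all(n1$truth$transitions$mode == "contrast"))
  expect_equal(nrow(n1$truth$transitions), 7L)
})

test_that("song_spec validates probabilities, reps and seed", {
  expect_error(song_spec(seed = 1, reps_range = c(0L, 5L)),
               class = "morphsong_input_error")
  expect_error(song_spec(seed = 1, mode_probabilities = c(timbre = 1)),
               class = "morphsong_input_error")
  expect_error(
    song_spec(seed = 1, mode_probabilities = c(timbre = 0.5, pitch = 0.2,
                                               stretch = 0.2, squeeze = 0.2,
                                               contrast = 0.2)),
    class = "morphsong_input_error")
  expect_error(song_spec(n_phrases = 5L), "seed")
})

test_that("write_song emits WAV, ground truth CSVs and a spec echo", {
  dir <- withr::local_tempdir()
  song <- generate_song(song_spec(n_phrases = 3L, seed = 2))
  paths <- write_song(song, file.path(dir, "demo"))
  expect_true(all(file.exists(paths)))
  clip <- load_audio(paths[["wav"]])
  expect_equal(length(clip$samples), length(song$clip$samples))
  syl <- read.csv(paths[["syllables"]])
  expect_equal(nrow(syl), nrow(song$truth$syllables))
  spec_echo <- jsonlite::read_json(paths[["spec"]])
  expect_equal(spec_echo$seed, 2L)
  expect_equal(spec_echo$n_phrases, 3L)
})
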