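# morphsong

Quantitative analysis of "morphing" in mockingbird song.

Mockingbirds sing phrases — trains of one syllable type repeated 3–5+
times, separated by minibreaths — and often glide between consecutive
phrases by conserving most acoustic qualities while changing one: pitch,
timbre, or tempo (stretch / squeeze). morphsong is for bioacousticians who
want to test whether that "morphing" impression is real acoustic structure
in a recording: it measures whether **adjacent phrases are more similar
than random distant phrases**, feature by feature, and labels each phrase
transition with its most salient morphing mode.

## What it computes

For every syllable pair the package performs dynamic time warping (DTW) on
the two amplitude envelopes — cost |a_i − b_j|, steps {(1,0),(0,1),(1,1)} —
and transfers the same warping path to the frequency and Wiener-entropy
contours, yielding four metrics:

1. **amplitude distance** — mean |Δ| of the time-warped normalized
   envelopes (internal syllable shape),
2. **frequency distance** — mean |Δ| of the warped spectral-centroid
   contours, in Hz (pitch),
3. **entropy distance** — mean |Δ| of the warped log10 spectral-flatness
   contours (timbre; 0 = noise-like, strongly negative = tonal),
4. **duration ratio** — shorter:longer syllable duration (tempo).

A phrase pair is scored by averaging each metric over all m × n syllable
pairs. Every phrase is compared with its successor ("adjacent") and with
10 random phrases outside a ±10-phrase window ("distant"); per feature, a
two-sided Welch t-test with Bonferroni correction (α = 0.05/4) decides
whether adjacency predicts similarity. A deterministic rule calibrated on
the song's own distant-pair quantiles labels each transition as
`timbre`, `pitch`, `stretch`, `squeeze`, or `contrast`.

A synthetic-song generator (harmonic stacks + shaped noise, phrases,
minibreaths, ground-truth morph modes) makes the whole pipeline testable
without field recordings.

## Worked example

Simulate a 60-phrase song with clearly separated morphs, run the full
pipeline, and test the adjacent-vs-distant hypothesis:

```r
library(morphsong)

spec <- song_spec(n_phrases = 60, seed = 7,
                  pitch_shift = c(1.3, 1.5),
                  duration_factor = c(2.4, 3.0),
                  noisiness_delta = c(0.12, 0.2))
song <- generate_song(spec)

ft   <- song_features(song$clip)
seg  <- segment_syllables(ft$amp, ft$ent, ent_threshold = -0.6)
syls <- extract_syllables(seg, ft$amp, ft$freq, ft$ent)
phr  <- group_into_phrases(syls)

cmp   <- compare_song(phr, seed = 7)
stats <- test_features(cmp)
print(stats, digits = 3)
```

```
         feature mean_adjacent sem_adjacent mean_distant sem_distant
1      amplitude        0.0425     3.89e-03     5.82e-02     0.00146
2      frequency      631.9893     1.08e+02     1.45e+03    39.27196
3        entropy        0.2879     4.61e-02     5.20e-01     0.01978
4 duration_ratio        0.6482     4.06e-02     5.86e-01     0.00964
  t_statistic  p_value corrected_alpha significant
1       -3.80 2.89e-04          0.0125        TRUE
2       -7.14 5.40e-10          0.0125        TRUE
3       -4.64 1.34e-05          0.0125        TRUE
4        1.49 1.41e-01          0.0125       FALSE
```

Adjacent phrases are significantly closer than distant ones in amplitude,
frequency and entropy (negative t: smaller distances), while the duration
ratio is not — morphing conserves most qualities across the phrase
boundary, and tempo morphs cut against duration similarity. Classifying
the 59 transitions against the song's own distant-pair distance quantiles:

```r
modes <- classify_song_transitions(phr, cmp)
mode_frequency_table(modes$mode)
```

```
      mode count proportion
1   timbre    21  0.3559322
2    pitch    13  0.2203390
3  stretch     9  0.1525424
4  squeeze    10  0.1694915
5 contrast     6  0.1016949
```

which agrees with the simulator's ground-truth modes on 73% of
transitions at these morph strengths.

Real recordings enter the same way: `load_audio("song.wav")`, optionally
`read_annotations()` for hand-drawn phrase boundaries, or the one-call
driver `run_analysis(run_config(audio = "song.wav", ...))`, which writes
the feature, segment, phrase, distance, statistics and mode tables plus a
parameter log. A thin CLI over the same functions lives at
`inst/cli/morphsong.R` (subcommands `simulate`, `analyze`, `classify`).

## Package layout

* `R/audio_io.R` — WAV reading/writing, `audio_clip`
* `R/feature_tracks.R` — envelope, mean frequency, Wiener entropy
* `R/segmentation.R` — dual-threshold syllable segmentation, label I/O
* `R/phrasing.R` — annotation-based and gap-based phrase grouping
* `R/distance.R` + `src/dtw.cpp` — DTW, warped distances, phrase scores
* `R/transition_stats.R` — adjacent-vs-distant sampling and tests
* `R/mode_classifier.R` — quantile-calibrated morph-mode labelling
* `R/synthetic_song.R` — templates, morph operators, song generator
* `R/pipeline.R` — `run_config` / `run_analysis` / `run_simulate`

See `vignettes/morphsong-methods.Rmd` for the full methods account:
model assumptions, parameter defaults and units, simulator design, and
known limitations.
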