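---
title: "Quantifying phrase morphing in mockingbird song: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phrase morphing in mockingbird song: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphsong)
```

## The scientific question

Northern mockingbirds sing long bouts organized as *phrases*: trains of one
syllable type repeated three to five or more times, separated by tiny
inspirations ("minibreaths"), before the bird switches to a new syllable
type. Human listeners often hear consecutive phrases *morph* into one
another — most acoustic qualities are conserved across the phrase boundary
while one (pitch, timbre, or tempo) changes. morphsong implements a
quantitative test of whether that impression reflects real acoustic
structure: are adjacent phrases measurably more similar than phrases far
apart in the song?

The pipeline has five stages: feature extraction, syllable segmentation,
phrase grouping, distance computation, and the adjacent-vs-distant
comparison with per-feature tests, plus a rule-based classifier that labels
each transition with a morphing mode. A parametric song simulator with
ground truth underpins every stage's tests.

## Feature contours

Three per-millisecond contours are extracted from mono PCM audio:

* **Amplitude envelope** — RMS amplitude in 10 ms windows stepped at 1 ms,
  then normalized within consecutive 4 s windows by the window maximum.
  The normalization removes slow intensity drift (a singer turning its
  head) that would otherwise dominate amplitude distances; it maps each
  window into 0..1, leaves all-zero windows at zero, and normalizes a final
  partial window by its own maximum.
* **Mean frequency** — the power-weighted spectral centroid per frame, in
  Hz. This is a distributional pitch measure, not a fundamental-frequency
  tracker; for a harmonic stack it sits between the partials, and for noise
  it sits at the centre of the occupied band. Digitally silent frames are
  assigned 0 Hz; after segmentation no frame inside a syllable is silent,
  so the fill value never enters a distance.
* **Wiener entropy** — log10 of spectral flatness (geometric over
  arithmetic mean of the short-time power spectrum). Zero for a flat,
  noise-like spectrum; strongly negative for tonal sounds. Values are
  clamped at a floor of −10: pure tones drive sidelobe bins into numerical
  underflow, where an unbounded log measures floating-point noise rather
  than signal. Silent frames also map to the floor, never to NaN.

Spectral frames are 10 ms, Hann-windowed, zero-padded to the next power of
two (256 points at 22.05 kHz), one frame per millisecond; frame *t* is
centred at *t* + 0.5 ms with edge frames shifted inward so every frame is
full length. All three tracks of a clip share one 0-based, half-open,
1 ms grid.

## Segmentation and phrasing

A millisecond is syllable material when the normalized envelope exceeds an
amplitude threshold **and** the Wiener entropy lies below an entropy
threshold (song is louder and more tonal than background). Maximal runs of
such milliseconds become syllables after two clean-up steps, in this
order: runs separated by gaps shorter than `min_gap_ms` (default 5 ms,
below the minibreath scale) are merged, then runs shorter than
`min_dur_ms` (default 10 ms) are discarded.

Thresholds are data-dependent and exposed as parameters. The package
defaults (`amp_threshold = 0.1`, `ent_threshold = -1.0`) suit strongly
tonal material. For the simulator's material we recommend and use
`ent_threshold = -0.6`: the simulated background noise sits near entropy
−0.25 and syllable interiors at or below −1.0, so a cutoff midway
maximizes the margin on both sides (boundary F1 across ten simulated songs
is 1.00 at −0.6 versus ~0.95 at −0.8). A percentile-based automatic mode
(`auto_thresholds()`, amplitude 60th / entropy 40th percentile) exists for
unattended batch use.

Phrases come either from user annotations (tab-separated label tracks or
CSV; annotations always override the heuristic) or from a gap rule: a new
phrase starts wherever the inter-syllable silence is at least
`phrase_gap_ms` (default 250 ms). The two silence scales in mockingbird
song — minibreaths of tens of ms and phrase pauses of hundreds — are well
separated, so a single threshold suffices. Single-syllable phrases are
legal; repertoire items sung once exist.

## Distances

For a syllable pair, dynamic time warping aligns the two **amplitude
envelopes**: cost |a_i − b_j|, step set {(1,0), (0,1), (1,1)}, no band
constraint, ties in backtracking broken diagonal-first (then vertical,
then horizontal) for determinism. The same warping path is then re-used,
unchanged, on the frequency and entropy contours — all features are
compared under one common time alignment, anchored on the envelope. Each
feature's distance is the mean over path steps of the pointwise absolute
difference. Durations, being scalars, are compared as the ratio
shorter:longer (1 = equal, small = strong tempo difference).

A phrase pair is compared all-against-all: every syllable of one phrase
against every syllable of the other, each of the four metrics averaged
arithmetically over the m × n comparisons (20 measurements for a
4-syllable vs 5-syllable pair). Averaging over all pairs, rather than
best-match assignment, keeps the score symmetric and insensitive to
syllable order within the phrase.

Why mean-over-path rather than resampling both contours to a common length
first: the path already expresses the optimal alignment, and averaging
|diff| along it treats compression and expansion symmetrically; it is also
the most direct reading of "mean distance between the time-warped
features". The amplitude DTW runs on the *normalized* envelope, since the
4 s normalization exists precisely to protect amplitude distances from
gain drift.

## Adjacent vs distant comparison

Every phrase with a successor is a focal phrase: its distance to the next
phrase is one "adjacent" score, and its distances to k = 10 phrases
sampled uniformly without replacement from outside a ±10-phrase window are
the "distant" scores — the null model for what similarity looks like when
adjacency plays no role. Focal phrases with fewer than 10 eligible distant
phrases are skipped (with a ±10 window this means songs need 31+ phrases
for full coverage). The sampling seed is recorded in every output.

Per feature, a two-sided Welch two-sample t-test compares the adjacent
scores against the pooled distant scores, with a Bonferroni-corrected
threshold of 0.05/4 (four features per song; the family size is a
parameter, since correcting across songs instead is defensible). We chose
the unpaired Welch form because no pairing structure links one adjacent
score to any particular distant score, and the two conditions have very
different group sizes (n vs 10n) and variances. Exactly identical
degenerate samples report t = 0, p = 1.

## Morphing-mode classification

Four morphing modes plus contrast are operationalized from their expected
distance signatures: a conserved feature should score "low" against the
song's own distant-pair distribution, the changed feature "high", tempo
changes a low duration ratio. Because absolute feature scales vary between
recordings, "low" and "high" are quantiles of the distant-pair scores
(below the 25th percentile; above the 50th) — the song is its own
reference. The decision rule, in order: tempo morph (low duration ratio,
everything else low; stretch vs squeeze by whether mean syllable duration
grew); timbre (entropy high, amplitude/frequency low, durations
undisturbed); pitch (frequency high, amplitude/entropy low, durations
undisturbed); contrast (amplitude, frequency and entropy all high).
Anything else falls back to the signature with the fewest violated
conditions, ties resolved timbre > pitch > squeeze > stretch (their
observed order of prevalence), then contrast. The rule is deterministic
and reports which conditions fired, so callers can flag likely mode
mixtures — single labels are a simplification; real transitions often
combine modes.

## The song simulator

Synthetic syllables are additive harmonic stacks (fundamental gliding
linearly between `f0_start` and `f0_end`, up to a few partials with a
per-partial dB rolloff) mixed with band-limited noise by weight
`noisiness`, under an attack/sustain/decay envelope with optional
sinusoidal amplitude modulation. This model was chosen because it controls
the four analysis axes almost independently: the envelope shape (ramps +
AM depth/rate) sets the amplitude contour, the stack sets mean frequency,
`noisiness` sets Wiener entropy, and duration is explicit.

Design notes, in the order we hit them:

* **Noise spectrum.** The noise component is synthesized in the frequency
  domain as a Gaussian bump (sigma = 0.6 × centre) over a small broadband
  floor (0.15 relative amplitude), re-centred once so the profile's power
  centroid lands exactly on the harmonic stack's centroid — the floor and
  the asymmetric truncation at 0/Nyquist would otherwise pull the noise
  centroid upward and make a timbre change leak into the frequency
  feature. With this profile a fully noisy syllable (`noisiness = 1`)
  measures entropy ≈ −0.65 and a mixture keeps its centroid within ~2%.
* **Entropy is steep in `noisiness`.** Entropy saturates quickly (≈ −6.7
  at 0, −1.3 at 0.2, −0.9 at 0.5), so the simulator keeps song syllables
  in the tonal regime (template noisiness ≤ 0.18, timbre morphs confined
  to 0..0.22) where segmentation margins are safe and entropy still spans
  five log units.
* **Envelope ramps.** Attack/decay ramps are square-root shaped and capped
  near 30 ms of absolute time: a long linear fade crosses any amplitude
  threshold far from the rendered boundary and smears detected onsets and
  offsets by more than the ±5 ms the evaluation tolerates.
* **Amplitude structure.** AM depth 0–0.55 at 15–60 Hz gives syllables
  internal envelope shape (whistle-like to pulsed), which is what makes
  the amplitude feature informative across templates; depth is capped so
  modulation valleys never approach the amplitude threshold.
* **Morph operators.** Pitch scales the whole f0 glide (direction
  randomized, constrained away from Nyquist and a 300 Hz floor); timbre
  shifts `noisiness` (direction chosen toward available headroom);
  stretch/squeeze scale duration by a factor > 1 (and scale the AM rate
  inversely — a slowed-down sound slows internally too); contrast draws a
  fresh independent template. Chained morphs are kept inside renderable
  bounds (durations 25–500 ms), flipping stretch to squeeze at the
  boundary when needed, and the mode actually applied is what ground truth
  records.

Default song structure follows the field description of mockingbird song:
3–5 repetitions per phrase, 30 ms minibreaths, 400 ms phrase gaps,
syllables 40–250 ms with fundamentals 1–6 kHz, background white noise at
25 dB SNR, 22.05 kHz sample rate, one mandatory RNG seed determining
everything. Morph-mode probabilities default to 0.2 each (morphing
probability 0.8 overall). A *null* song draws every phrase template
independently — the fixture for false-positive-rate checks.

What the simulator does **not** emulate: real mimicry (heterospecific call
structure), two-voice syrinx phenomena, reverberation and varying
recording distance, overlapping singers, and combination morphs (each
simulated transition changes exactly one quality). Passing recovery tests
on this material therefore shows the pipeline detects morphing structure
of the kind and strength simulated — it does not validate the thresholds
or effect sizes on field recordings.

## Problem sizes and test design

The packaged checks run at desk scale, chosen once: effect recovery uses
20 songs of 150 phrases with morph probability 0.8 (the spec-level
condition for a detectable effect) and expects the Bonferroni-corrected
adjacent < distant result for amplitude, frequency and entropy in ≥ 90% of
seeds; false-positive control uses 50 null songs of 40 phrases (40 is
comfortably above the 31-phrase minimum the ±10/k = 10 sampling scheme
needs) and expects per-feature rejection ≤ 10%; segmentation recovery uses
10 songs of 15 phrases (boundary F1 at ±5 ms); classifier recovery uses 25
transitions per mode with strongly separated parameters (pitch shift
30–50%, duration factor 2.4–3.0, noisiness change 0.5–0.65, fundamentals
kept at 1.0–2.2 kHz so no partial crosses Nyquist under a pitch shift —
a near-Nyquist harmonic appearing or vanishing is a genuine timbre change
and would contaminate pitch-mode ground truth).

Numerical conventions collected in one place: DTW ties break
diagonal/vertical/horizontal; duration ratios live in (0, 1]; entropy in
[−10, 0]; quantiles are R type 7; degenerate identical samples test as
t = 0, p = 1; constant distant-pair distances make quantile calibration
degenerate and raise an input error rather than emitting meaningless
labels; all phrase indices are 1-based.

## Known limitations

* Mean frequency is a centroid, not a pitch tracker; strongly noisy
  syllables read near the centre of their noise band regardless of any
  perceived pitch.
* The classifier assigns exactly one mode; real transitions often combine
  modes, and the fired-condition report is only a coarse mixture
  diagnostic.
* Segmentation thresholds are per-recording settings; no universal default
  exists, and the automatic percentile mode is a convenience, not a
  calibration.
* The adjacent-vs-distant test treats phrase comparisons as independent
  samples; within-song correlation (the same focal phrase contributes 11
  scores) is not modelled. A mixed-effects extension would be the natural
  next step for multi-bird inference.
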