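#' Morphing mode labels
#'
#' The four morphing modes -- `pitch` (frequency shifted, rest conserved),
#' `timbre` (tone quality changed, rest conserved), `stretch` (slowed
#' down), `squeeze` (sped up) -- plus `contrast` (no salient similarity
#' between pre- and post-transition phrases).
#'
#' @return character vector of the five labels.
#' @export
morph_modes <- function() c("timbre", "pitch", "stretch", "squeeze", "contrast")

#' Calibrate low/high thresholds from distant-pair distances
#'
#' Because raw feature scales differ between recordings, "low" and "high"
#' are operationalized as quantiles of the song's own distant-pair distance
#' distributions: a distance below the `low_q` quantile of distant pairs is
#' "low", one above the `high_q` quantile is "high". The duration-ratio
#' "low" cutoff is the `low_q` quantile of distant-pair duration ratios.
#'
#' @param distant data.frame of distant-pair scores with columns
#'   `amp_dist`, `freq_dist`, `ent_dist`, `dur_ratio` (e.g. the distant
#'   rows of [compare_song()] output).
#' @param low_q,high_q quantile levels, `low_q < high_q`.
#' @return An object of class `mode_thresholds`: per-feature `low`/`high`
#'   cutoffs and `dur_low`.
#' @export
calibrate_thresholds <- function(distant, low_q = 0.25, high_q = 0.5) {
  cols <- c("amp_dist", "freq_dist", "ent_dist", "dur_ratio")
  if (!all(cols %in% names(distant)))
    ms_input_error("calibrate_thresholds: missing distance columns")
  if (nrow(distant) < 20L)
    ms_input_error("calibrate_thresholds: need >= 20 distant-pair scores, got ",
                   nrow(distant))
  if (low_q >= high_q)
    ms_input_error("calibrate_thresholds: low_q must be < high_q")
  q <- function(v, p) as.numeric(quantile(v, p))
  th <- list(
    amp = c(low = q(distant$amp_dist, low_q), high = q(distant$amp_dist, high_q)),
    freq = c(low = q(distant$freq_dist, low_q), high = q(distant$freq_dist, high_q)),
    ent = c(low = q(distant$ent_dist, low_q), high = q(distant$ent_dist, high_q)),
    dur_low = q(distant$dur_ratio, low_q),
    low_q = low_q, high_q = high_q)
  for (f in c("amp", "freq", "ent"))
    if (th[[f]]["low"] >= th[[f]]["high"])
      ms_input_error("calibrate_thresholds: degenerate (constant) distant ",
                     f, " distances; low and high cutoffs coincide")
  structure(th, class = "mode_thresholds")
}

#' @export
print.mode_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<mode_thresholds (q %.2f/%.2f): amp [%.3g, %.3g], ",
                     "freq [%.3g, %.3g] Hz, ent [%.3g, %.3g], dur_low %.3f>\n"),
              x$low_q, x$high_q, x$amp["low"], x$amp["high"],
              x$freq["low"], x$freq["high"], x$ent["low"], x$ent["high"],
              x$dur_low))
  invisible(x)
}

#' Classify one phrase transition into a morphing mode
#'
#' Applies, in order, the expected distance signatures of the morphing
#' modes: a conserved feature should show a "low" distance, the changed
#' feature a "high" distance, and tempo changes a "low" duration ratio.
#' Specifically: (1) low duration ratio with low amplitude/frequency/
#' entropy distances is a tempo morph -- `stretch` if the post-transition
#' phrase's mean syllable duration exceeds the pre-transition one, else
#' `squeeze`; (2) high entropy distance with low amplitude/frequency
#' distances and undisturbed durations is `timbre`; (3) high frequency
#' distance with low amplitude/entropy distances and undisturbed durations
#' is `pitch`; (4) amplitude, frequency and entropy distances all high is
#' `contrast`; (5) otherwise the mode violating the fewest of its
#' signature conditions wins, ties broken in the order timbre, pitch,
#' squeeze, stretch (the observed order of prevalence), then contrast.
#'
#' @param pd a [pair_distance()] for the transition (pre vs post phrase).
#' @param durations numeric length-2 vector: mean syllable duration (ms) of
#'   the pre- and post-transition phrase.
#' @param th a [calibrate_thresholds()] result.
#' @return A single mode label (character); the logical vector of fired
#'   signature conditions is attached as attribute `"conditions"`.
#' @export
classify_transition <- function(pd, durations, th) {
  if (!inherits(th, "mode_thresholds"))
    ms_input_error("classify_transition: th must be mode_thresholds")
  amp_low <- pd$amp_dist < th$amp[["low"]];  amp_high <- pd$amp_dist > th$amp[["high"]]
  freq_low <- pd$freq_dist < th$freq[["low"]]; freq_high <- pd$freq_dist > th$freq[["high"]]
  ent_low <- pd$ent_dist < th$ent[["low"]];  ent_high <- pd$ent_dist > th$ent[["high"]]
  dur_low <- pd$dur_ratio < th$dur_low
  post_longer <- durations[2] > durations[1]

  conds <- c(amp_low = amp_low, amp_high = amp_high, freq_low = freq_low,
             freq_high = freq_high, ent_low = ent_low, ent_high = ent_high,
             dur_low = dur_low, post_longer = post_longer)

  label <-
    if (dur_low && amp_low && freq_low && ent_low) {
      if (post_longer) "stretch" else "squeeze"
    } else if (ent_high && amp_low && freq_low && !dur_low) {
      "timbre"
    } else if (freq_high && amp_low && ent_low && !dur_low) {
      "pitch"
    } else if (amp_high && freq_high && ent_high) {
      "contrast"
    } else {
      # fallback: fewest violated signature conditions
      violations <- c(
        timbre  = sum(!c(ent_high, amp_low, freq_low, !dur_low)),
        pitch   = sum(!c(freq_high, amp_low, ent_low, !dur_low)),
        squeeze = sum(!c(dur_low, amp_low, freq_low, ent_low, !post_longer)),
        stretch = sum(!c(dur_low, amp_low, freq_low, ent_low, post_longer)),
        contrast = sum(!c(amp_high, freq_high, ent_high)))
      names(violations)[which.min(violations)]  # order above breaks ties
    }
  structure(label, conditions = conds)
}

#' Classify every transition of a song
#'
#' Calibrates thresholds from the distant-pair rows of a [compare_song()]
#' table (unless `th` is supplied), computes the pre/post phrase distance
#' for each consecutive phrase pair, and labels each transition.
#'
#' @param phrases list of [phrase()]s.
#' @param comparisons [compare_song()] output used for calibration; ignored
#'   when `th` is given.
#' @param th optional pre-calibrated [calibrate_thresholds()] object.
#' @param low_q,high_q passed to [calibrate_thresholds()].
#' @return data.frame with one row per transition: `phrase_index` (the
#'   pre-transition phrase), `mode`, the four distances, and
#'   `conditions_fired` (comma-separated fired condition names).
#' @export
classify_song_transitions <- function(phrases, comparisons = NULL, th = NULL,
                                      low_q = 0.25, high_q = 0.5) {
  if (is.null(th)) {
    if (is.null(comparisons))
      ms_input_error("classify_song_transitions: need comparisons or thresholds")
    th <- calibrate_thresholds(
      comparisons[comparisons$type == "distant", , drop = FALSE], low_q, high_q)
  }
  n <- length(phrases)
  if (n < 2L) ms_input_error("classify_song_transitions: need >= 2 phrases")
  rows <- lapply(seq_len(n - 1L), function(i) {
    pd <- phrase_distance(phrases[[i]], phrases[[i + 1L]])
    durs <- c(phrase_mean_duration(phrases[[i]]),
              phrase_mean_duration(phrases[[i + 1L]]))
    lab <- classify_transition(pd, durs, th)
    conds <- attr(lab, "conditions")
    data.frame(phrase_index = i, mode = as.character(lab),
               amp_dist = pd$amp_dist, freq_dist = pd$freq_dist,
               ent_dist = pd$ent_dist, dur_ratio = pd$dur_ratio,
               conditions_fired = paste(names(conds)[conds], collapse = ","))
  })
  do.call(rbind, rows)
}

#' Mode frequency table
#'
#' @param modes character vector of mode labels (>= 1).
#' @return data.frame with `mode`, `count`, `proportion` for every mode in
#'   [morph_modes()]; counts sum to `length(modes)`, proportions to 1.
#' @export
mode_frequency_table <- function(modes) {
  if (length(modes) == 0L)
    ms_input_error("mode_frequency_table: no transitions")
  bad <- setdiff(unique(modes), morph_modes())
  if (length(bad))
    ms_input_error("mode_frequency_table: unknown mode label(s): ",
                   paste(bad, collapse = ", "))
  counts <- table(factor(modes, levels = morph_modes()))
  data.frame(mode = names(counts), count = as.integer(counts),
             proportion = as.numeric(counts) / length(modes))
}
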