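#' Dynamic time warping of two value sequences
#'
#' Finds the warping path minimizing the summed absolute difference
#' `|a[i] - b[j]|` over all admissible paths with the symmetric step set
#' \{(1,0), (0,1), (1,1)\} and no window constraint. Ties in backtracking
#' are broken deterministically (diagonal, then vertical, then horizontal).
#'
#' The path found on the amplitude envelopes of two syllables is re-used
#' ("transferred") to their frequency and entropy contours by
#' [warped_distance()], so all features are compared under one common time
#' alignment.
#'
#' @param a,b numeric sequences (length >= 1).
#' @return list with `path` (an n_steps x 2 integer matrix of 1-based index
#'   pairs, starting at (1,1), ending at (length(a), length(b))) and `cost`
#'   (the minimal total cost).
#' @export
dtw_path <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    ms_input_error("dtw_path: sequences must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    ms_input_error("dtw_path: sequences must be finite")
  .dtw_path_cpp(as.numeric(a), as.numeric(b))
}

#' Mean distance of two sequences along a fixed warping path
#'
#' The mean over warping-path steps of the pointwise absolute difference
#' `|fa[i] - fb[j]|` -- the mean Euclidean distance between the time-warped
#' feature contours.
#'
#' @param path warping path matrix (as in [dtw_path()]`$path`).
#' @param fa,fb numeric sequences the path indexes into.
#' @return mean distance (numeric scalar >= 0).
#' @export
warped_distance <- function(path, fa, fb) {
  if (is.list(path) && !is.null(path$path)) path <- path$path
  if (!is.matrix(path) || ncol(path) != 2L)
    ms_input_error("warped_distance: path must be a 2-column index matrix")
  if (max(path[, 1]) > length(fa) || max(path[, 2]) > length(fb) ||
      min(path) < 1L)
    ms_input_error("warped_distance: path index out of range")
  mean(abs(fa[path[, 1]] - fb[path[, 2]]))
}

#' Duration ratio of two syllables
#'
#' Shorter duration divided by longer duration; 1 means equal durations,
#' low values indicate temporal stretching or squeezing.
#'
#' @param dur_a,dur_b durations in ms (> 0).
#' @return ratio in (0, 1].
#' @export
duration_ratio <- function(dur_a, dur_b) {
  if (!is.finite(dur_a) || !is.finite(dur_b) || dur_a <= 0 || dur_b <= 0)
    ms_input_error("duration_ratio: durations must be positive")
  min(dur_a, dur_b) / max(dur_a, dur_b)
}

#' Four-metric distance container
#'
#' @param amp_dist,freq_dist,ent_dist mean warped distances (>= 0) for the
#'   amplitude, frequency (Hz) and Wiener entropy contours.
#' @param dur_ratio duration ratio in (0, 1].
#' @param n_comparisons number of syllable pairs averaged (1 for a single
#'   syllable pair).
#' @return An object of class `pair_distance`.
#' @export
pair_distance <- function(amp_dist, freq_dist, ent_dist, dur_ratio,
                          n_comparisons = 1L) {
  vals <- c(amp_dist, freq_dist, ent_dist, dur_ratio)
  if (!all(is.finite(vals)))
    ms_input_error("pair_distance: all fields must be finite")
  if (amp_dist < 0 || freq_dist < 0 || ent_dist < 0)
    ms_input_error("pair_distance: distances must be >= 0")
  if (dur_ratio <= 0 || dur_ratio > 1)
    ms_input_error("pair_distance: dur_ratio must be in (0, 1]")
  structure(list(amp_dist = amp_dist, freq_dist = freq_dist,
                 ent_dist = ent_dist, dur_ratio = dur_ratio,
                 n_comparisons = as.integer(n_comparisons)),
            class = "pair_distance")
}

#' @export
print.pair_distance <- function(x, ...) {
  cat(sprintf(paste0("<pair_distance: amp %.4g, freq %.4g Hz, ent %.4g, ",
                     "dur_ratio %.3f (%d comparison%s)>\n"),
              x$amp_dist, x$freq_dist, x$ent_dist, x$dur_ratio,
              x$n_comparisons, if (x$n_comparisons == 1L) "" else "s"))
  invisible(x)
}

#' Distance between two syllables
#'
#' DTW is performed once, on the two amplitude envelopes; the resulting
#' warping path is then applied unchanged to the frequency and entropy
#' contours, and the mean absolute difference along the path is reported
#' per feature. Durations are compared as their ratio.
#'
#' @param sa,sb [syllable()] objects with non-empty contours.
#' @return A [pair_distance()].
#' @export
syllable_distance <- function(sa, sb) {
  v <- .syllable_dist4_cpp(sa$amp, sb$amp, sa$freq, sb$freq, sa$ent, sb$ent)
  pair_distance(
    amp_dist = v[1], freq_dist = v[2], ent_dist = v[3],
    dur_ratio = duration_ratio(sa$duration_ms, sb$duration_ms))
}

#' Distance between two phrases (all syllable pairs)
#'
#' Compares every syllable of the first phrase with every syllable of the
#' second in a pairwise fashion (m x n comparisons) and averages each of
#' the four metrics arithmetically over all comparisons. A 4-syllable
#' phrase against a 5-syllable phrase therefore averages 20 measurements
#' per feature.
#'
#' @param pa,pb [phrase()] objects (non-empty).
#' @return A [pair_distance()] whose `n_comparisons` is m x n.
#' @export
phrase_distance <- function(pa, pb) {
  if (!inherits(pa, "phrase") || !inherits(pb, "phrase"))
    ms_input_error("phrase_distance: arguments must be phrases")
  m <- length(pa$syllables)
  n <- length(pb$syllables)
  if (m == 0L || n == 0L) ms_input_error("phrase_distance: empty phrase")
  acc <- matrix(0, m * n, 4)
  k <- 0L
  for (i in seq_len(m)) {
    sa <- pa$syllables[[i]]
    for (j in seq_len(n)) {
      k <- k + 1L
      sb <- pb$syllables[[j]]
      v <- .syllable_dist4_cpp(sa$amp, sb$amp, sa$freq, sb$freq,
                               sa$ent, sb$ent)
      acc[k, ] <- c(v[1], v[2], v[3],
                    duration_ratio(sa$duration_ms, sb$duration_ms))
    }
  }
  mu <- colMeans(acc)
  pair_distance(mu[1], mu[2], mu[3], mu[4], n_comparisons = m * n)
}

#' Tabulate pairwise phrase distances
#'
#' @param phrases list of [phrase()]s.
#' @param pairs 2-column matrix of phrase index pairs to compare; default
#'   all unordered pairs.
#' @return data.frame with `phrase_a`, `phrase_b`, `n_comparisons`,
#'   `amp_dist`, `freq_dist`, `ent_dist`, `dur_ratio`.
#' @export
phrase_distance_table <- function(phrases, pairs = NULL) {
  if (is.null(pairs)) {
    idx <- seq_along(phrases)
    pairs <- t(utils::combn(idx, 2L))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    d <- phrase_distance(phrases[[pairs[r, 1]]], phrases[[pairs[r, 2]]])
    data.frame(phrase_a = pairs[r, 1], phrase_b = pairs[r, 2],
               n_comparisons = d$n_comparisons, amp_dist = d$amp_dist,
               freq_dist = d$freq_dist, ent_dist = d$ent_dist,
               dur_ratio = d$dur_ratio)
  })
  do.call(rbind, rows)
}
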