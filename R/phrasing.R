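#' A phrase: an ordered train of repeated syllables
#'
#' @param index 1-based position of the phrase in the song.
#' @param syllables list of [syllable()] objects sorted by onset (>= 1).
#' @param label optional text label.
#' @return An object of class `phrase`.
#' @export
phrase <- function(index, syllables, label = NA_character_) {
  if (length(syllables) == 0L)
    ms_input_error("phrase: needs at least one syllable")
  onsets <- vapply(syllables, `[[`, integer(1), "onset_ms")
  if (is.unsorted(onsets))
    ms_input_error("phrase: syllables must be sorted by onset")
  structure(list(index = as.integer(index), syllables = syllables,
                 label = label),
            class = "phrase")
}

#' @export
print.phrase <- function(x, ...) {
  cat(sprintf("<phrase %d: %d syllables, [%d, %d) ms%s>\n", x$index,
              length(x$syllables), x$syllables[[1]]$onset_ms,
              x$syllables[[length(x$syllables)]]$offset_ms,
              if (is.na(x$label)) "" else paste0(", '", x$label, "'")))
  invisible(x)
}

#' Mean syllable duration of a phrase, in ms
#' @param p a [phrase()].
#' @return numeric scalar.
#' @export
phrase_mean_duration <- function(p) {
  mean(vapply(p$syllables, `[[`, integer(1), "duration_ms"))
}

#' Read phrase annotations
#'
#' Reads user-supplied phrase intervals from a tab-separated label file
#' (start_s, end_s, label) or a CSV with `onset_ms`, `offset_ms` and
#' optionally `label`. Intervals are returned sorted; overlapping phrase
#' intervals are an error.
#'
#' @param path annotation file path.
#' @return data.frame with `onset_ms`, `offset_ms`, `label`.
#' @export
read_annotations <- function(path) {
  iv <- read_segments(path)
  if (nrow(iv) > 1L && any(iv$onset_ms[-1] < iv$offset_ms[-nrow(iv)]))
    ms_input_error("read_annotations: overlapping phrase intervals in ", path)
  iv
}

#' Group syllables into phrases by inter-syllable gap
#'
#' The automatic fallback when no phrase annotations are supplied: a new
#' phrase starts whenever the silent gap between consecutive syllables is at
#' least `phrase_gap_ms`. Gaps within phrases ("minibreaths") are much
#' shorter than pauses between phrases, so a single gap threshold separates
#' the two scales.
#'
#' @param syllables list of [syllable()]s sorted by onset, non-overlapping.
#' @param phrase_gap_ms minimum silent gap that separates phrases (ms).
#' @return list of [phrase()]s with consecutive 1-based indices.
#' @export
group_into_phrases <- function(syllables, phrase_gap_ms = 250L) {
  if (length(syllables) == 0L) return(list())
  onsets <- vapply(syllables, `[[`, integer(1), "onset_ms")
  offsets <- vapply(syllables, `[[`, integer(1), "offset_ms")
  gaps <- onsets[-1] - offsets[-length(offsets)]
  breaks <- c(FALSE, gaps >= phrase_gap_ms)
  grp <- cumsum(breaks) + 1L
  lapply(seq_len(max(grp)), function(g)
    phrase(g, syllables[grp == g]))
}

#' Assign syllables to annotated phrase intervals
#'
#' Each syllable is assigned to the interval containing its onset; syllables
#' outside all intervals are dropped (a warning reports how many).
#'
#' @param syllables list of [syllable()]s.
#' @param intervals data.frame of non-overlapping phrase intervals
#'   (`onset_ms`, `offset_ms`, optional `label`), as from
#'   [read_annotations()].
#' @return list of [phrase()]s indexed in temporal order.
#' @export
assign_syllables_to_phrases <- function(syllables, intervals) {
  if (nrow(intervals) == 0L || length(syllables) == 0L) return(list())
  intervals <- intervals[order(intervals$onset_ms), , drop = FALSE]
  onsets <- vapply(syllables, `[[`, integer(1), "onset_ms")
  which_iv <- findInterval(onsets, intervals$onset_ms)
  inside <- which_iv >= 1L & onsets < intervals$offset_ms[pmax(which_iv, 1L)]
  n_drop <- sum(!inside)
  if (n_drop > 0L)
    warning(n_drop, " syllable(s) outside all phrase intervals were dropped")
  used <- sort(unique(which_iv[inside]))
  phrases <- lapply(seq_along(used), function(k) {
    iv <- used[k]
    phrase(k, syllables[inside & which_iv == iv],
           label = if ("label" %in% names(intervals))
                     as.character(intervals$label[iv]) else NA_character_)
  })
  phrases
}

#' Summarize phrases as a table
#'
#' @param phrases list of [phrase()]s.
#' @return data.frame with `phrase_index`, `onset_ms`, `offset_ms`,
#'   `n_syllables`, `label`.
#' @export
phrase_table <- function(phrases) {
  data.frame(
    phrase_index = vapply(phrases, `[[`, integer(1), "index"),
    onset_ms = vapply(phrases, function(p) p$syllables[[1]]$onset_ms, integer(1)),
    offset_ms = vapply(phrases, function(p)
      p$syllables[[length(p$syllables)]]$offset_ms, integer(1)),
    n_syllables = vapply(phrases, function(p) length(p$syllables), integer(1)),
    label = vapply(phrases, function(p) as.character(p$label), character(1)))
}
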