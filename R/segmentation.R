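#' Segment syllables with a dual amplitude/entropy threshold
#'
#' A millisecond belongs to a syllable when the normalized amplitude
#' envelope is louder than `amp_threshold` AND the Wiener entropy is lower
#' (more tone-like) than `ent_threshold`. Maximal runs of such milliseconds
#' are taken as candidate syllables; runs separated by gaps shorter than
#' `min_gap_ms` are merged, then runs shorter than `min_dur_ms` are
#' discarded.
#'
#' @param amp normalized amplitude `feature_track`.
#' @param ent Wiener entropy `feature_track` on the same time base.
#' @param amp_threshold amplitude threshold (on the 0..1 normalized scale).
#' @param ent_threshold Wiener entropy threshold (log10 units, <= 0).
#' @param min_dur_ms minimum syllable duration (ms).
#' @param min_gap_ms gaps shorter than this are merged (ms).
#' @return A data.frame with integer columns `onset_ms`, `offset_ms`
#'   (half-open intervals, sorted, non-overlapping).
#' @export
segment_syllables <- function(amp, ent, amp_threshold = 0.1,
                              ent_threshold = -1.0,
                              min_dur_ms = 10L, min_gap_ms = 5L) {
  if (!inherits(amp, "feature_track") || !inherits(ent, "feature_track"))
    ms_input_error("segment_syllables: amp and ent must be feature_tracks")
  if (length(amp) != length(ent) || amp$start_ms != ent$start_ms)
    ms_input_error("segment_syllables: amp and ent tracks have mismatched time bases (",
                   length(amp), " vs ", length(ent), " ms)")
  if (!is.finite(amp_threshold) || !is.finite(ent_threshold))
    ms_input_error("segment_syllables: thresholds must be finite")

  active <- amp$values > amp_threshold & ent$values < ent_threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0L)
    return(data.frame(onset_ms = integer(0), offset_ms = integer(0)))
  seg <- cbind(starts[on], ends[on])  # 1-based inclusive, track units

  # merge across short gaps
  if (nrow(seg) > 1L) {
    keep_on <- rep(TRUE, nrow(seg))
    for (i in 2:nrow(seg)) {
      gap <- seg[i, 1] - seg[i - 1, 2] - 1L
      if (gap < min_gap_ms) {
        seg[i, 1] <- seg[i - 1, 1]
        keep_on[i - 1] <- FALSE
      }
    }
    # after chained merges the last row of each merged group holds the union
    seg <- seg[keep_on, , drop = FALSE]
  }

  dur <- seg[, 2] - seg[, 1] + 1L
  seg <- seg[dur >= min_dur_ms, , drop = FALSE]
  data.frame(onset_ms = amp$start_ms + seg[, 1] - 1L,
             offset_ms = amp$start_ms + seg[, 2])
}

#' Percentile-based automatic thresholds
#'
#' Convenience for unattended use: the amplitude threshold is a percentile
#' of the normalized envelope and the entropy threshold a percentile of the
#' entropy track.
#'
#' @param amp normalized amplitude `feature_track`.
#' @param ent entropy `feature_track`.
#' @param amp_q,ent_q quantile levels (defaults 0.6 and 0.4).
#' @return list with `amp_threshold` and `ent_threshold`.
#' @export
auto_thresholds <- function(amp, ent, amp_q = 0.6, ent_q = 0.4) {
  list(amp_threshold = as.numeric(quantile(amp$values, amp_q)),
       ent_threshold = as.numeric(quantile(ent$values, ent_q)))
}

#' A segmented syllable with its three feature contours
#'
#' @param onset_ms,offset_ms half-open ms interval `[onset, offset)`.
#' @param amp,freq,ent numeric contour vectors of length
#'   `offset_ms - onset_ms`.
#' @return An object of class `syllable` with fields `onset_ms`,
#'   `offset_ms`, `duration_ms`, `amp`, `freq`, `ent`.
#' @export
syllable <- function(onset_ms, offset_ms, amp, freq, ent) {
  dur <- offset_ms - onset_ms
  if (dur <= 0) ms_input_error("syllable: offset must exceed onset")
  if (length(amp) != dur || length(freq) != dur || length(ent) != dur)
    ms_input_error("syllable: contour lengths must equal duration (", dur, " ms)")
  structure(list(onset_ms = as.integer(onset_ms),
                 offset_ms = as.integer(offset_ms),
                 duration_ms = as.integer(dur),
                 amp = as.numeric(amp), freq = as.numeric(freq),
                 ent = as.numeric(ent)),
            class = "syllable")
}

#' @export
print.syllable <- function(x, ...) {
  cat(sprintf("<syllable [%d, %d) ms, %d ms>\n", x$onset_ms, x$offset_ms,
              x$duration_ms))
  invisible(x)
}

#' Cut syllable contours out of the feature tracks
#'
#' @param segments data.frame with `onset_ms`, `offset_ms` (as returned by
#'   [segment_syllables()]).
#' @param amp,freq,ent the song's three `feature_track`s.
#' @return A list of [syllable()] objects, one per segment.
#' @export
extract_syllables <- function(segments, amp, freq, ent) {
  if (nrow(segments) == 0L) return(list())
  n <- length(amp)
  base <- amp$start_ms
  lapply(seq_len(nrow(segments)), function(i) {
    on <- segments$onset_ms[i]
    off <- segments$offset_ms[i]
    i0 <- on - base + 1L
    i1 <- off - base
    if (i0 < 1L || i1 > n || i0 > i1)
      ms_input_error("extract_syllables: segment [", on, ", ", off,
                     ") outside track range")
    idx <- i0:i1
    syllable(on, off, amp$values[idx], freq$values[idx], ent$values[idx])
  })
}

#' Read/write syllable segments as label tracks or CSV
#'
#' `write_segments` writes either a tab-separated label file
#' (start_s, end_s, label; the dialect audio editors import) or a CSV with
#' `onset_ms`, `offset_ms`. `read_segments` reads both.
#'
#' @param segments data.frame with `onset_ms`, `offset_ms` and optionally
#'   `label`.
#' @param path file path; `.csv` selects the CSV dialect, anything else the
#'   tab-separated label dialect.
#' @return `path` (write) or a segments data.frame (read).
#' @export
write_segments <- function(segments, path) {
  lab <- if ("label" %in% names(segments)) segments$label
         else rep("syll", nrow(segments))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(data.frame(onset_ms = segments$onset_ms,
                         offset_ms = segments$offset_ms, label = lab),
              path, row.names = FALSE)
  } else {
    df <- data.frame(start_s = segments$onset_ms / 1000,
                     end_s = segments$offset_ms / 1000, label = lab)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) ms_input_error("read_segments: no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- read.csv(path)
    if (!all(c("onset_ms", "offset_ms") %in% names(df)))
      ms_input_error("read_segments: CSV needs onset_ms, offset_ms columns")
    out <- data.frame(onset_ms = as.integer(df$onset_ms),
                      offset_ms = as.integer(df$offset_ms),
                      label = if ("label" %in% names(df)) as.character(df$label)
                              else NA_character_)
  } else {
    if (file.size(path) == 0L)
      return(data.frame(onset_ms = integer(0), offset_ms = integer(0),
                        label = character(0)))
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
      ms_input_error("read_segments: label file needs start and end columns")
    out <- data.frame(onset_ms = as.integer(round(df[[1]] * 1000)),
                      offset_ms = as.integer(round(df[[2]] * 1000)),
                      label = if (ncol(df) >= 3L) as.character(df[[3]])
                              else NA_character_)
  }
  if (any(out$offset_ms <= out$onset_ms))
    ms_input_error("read_segments: interval with end <= start in ", path)
  out[order(out$onset_ms), , drop = FALSE]
}
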