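#' Sample distant phrases for one focal phrase
#'
#' Draws `k` distinct phrase indices uniformly without replacement from all
#' phrases outside the `exclusion`-phrase window around the focal phrase
#' (indices `d` with `|d - focal| > exclusion`; the focal phrase and its
#' successor are inside the window and therefore never sampled). Uses the
#' current R RNG state, so wrap in a seed for reproducibility.
#'
#' @param focal 1-based focal phrase index.
#' @param n_phrases number of phrases in the song.
#' @param k number of distant phrases to sample.
#' @param exclusion half-width of the excluded window (phrases).
#' @return Integer vector of `k` indices, or `NULL` when fewer than `k`
#'   eligible phrases exist (the caller should skip this focal phrase).
#' @export
sample_distant_phrases <- function(focal, n_phrases, k = 10L,
                                   exclusion = 10L) {
  eligible <- which(abs(seq_len(n_phrases) - focal) > exclusion)
  if (length(eligible) < k) {
    ms_log("focal phrase ", focal, " skipped: only ", length(eligible),
           " eligible distant phrases (need ", k, ")")
    return(NULL)
  }
  sort(sample(eligible, k))
}

#' Adjacent vs distant phrase comparisons for a whole song
#'
#' For every phrase with a successor, computes the phrase distance to that
#' successor ("adjacent") and to `k` randomly sampled distant phrases
#' outside a `exclusion`-phrase window ("distant"). Focal phrases with too
#' few eligible distant phrases are skipped.
#'
#' @param phrases list of [phrase()]s (>= 2).
#' @param k distant phrases sampled per focal phrase.
#' @param exclusion half-width of the excluded window (phrases).
#' @param seed integer RNG seed; recorded in the result.
#' @return A data.frame with one row per phrase-pair comparison: columns
#'   `focal_index`, `partner_index`, `type` ("adjacent"/"distant"),
#'   `n_comparisons`, `amp_dist`, `freq_dist`, `ent_dist`, `dur_ratio`.
#'   The seed, `k` and `exclusion` are attached as attributes.
#' @export
compare_song <- function(phrases, k = 10L, exclusion = 10L, seed = 1L) {
  n <- length(phrases)
  if (n < 2L)
    ms_input_error("compare_song: need at least 2 phrases, got ", n)
  rows <- vector("list", n)
  withr_seed <- function(code) {  # keep caller RNG state untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code()
  }
  one_row <- function(focal, partner, type, d)
    data.frame(focal_index = focal, partner_index = partner, type = type,
               n_comparisons = d$n_comparisons, amp_dist = d$amp_dist,
               freq_dist = d$freq_dist, ent_dist = d$ent_dist,
               dur_ratio = d$dur_ratio)
  withr_seed(function() {
    for (i in seq_len(n - 1L)) {
      distant_idx <- sample_distant_phrases(i, n, k, exclusion)
      if (is.null(distant_idx)) next
      adj <- phrase_distance(phrases[[i]], phrases[[i + 1L]])
      part <- list(one_row(i, i + 1L, "adjacent", adj))
      for (d in distant_idx)
        part <- c(part, list(one_row(i, d, "distant",
                                     phrase_distance(phrases[[i]], phrases[[d]]))))
      rows[[i]] <<- do.call(rbind, part)
    }
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    ms_input_error("compare_song: no focal phrase had enough distant phrases")
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "k") <- k
  attr(out, "exclusion") <- exclusion
  out
}

# Welch two-sample t-test with the package's degenerate-sample convention:
# element-wise identical (zero-variance, equal-mean) samples give t = 0,
# p = 1 rather than NaN.
ms_welch <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, p = 1))
    # two distinct constants: infinitely strong separation
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Per-feature adjacent-vs-distant tests
#'
#' For each of the four features, runs a two-sided Welch two-sample t-test
#' of the adjacent-pair scores against the pooled distant-pair scores and
#' applies a Bonferroni correction (`corrected_alpha = alpha /
#' n_tests_for_correction`). Means and standard errors of both conditions
#' are reported for plotting.
#'
#' @param comparisons data.frame from [compare_song()].
#' @param n_tests_for_correction Bonferroni family size (default 4, the
#'   four features tested per bird).
#' @param alpha uncorrected significance level.
#' @return data.frame with one row per feature: `feature`, `mean_adjacent`,
#'   `sem_adjacent`, `mean_distant`, `sem_distant`, `t_statistic`,
#'   `p_value`, `corrected_alpha`, `significant`.
#' @export
test_features <- function(comparisons, n_tests_for_correction = 4L,
                          alpha = 0.05) {
  features <- c(amplitude = "amp_dist", frequency = "freq_dist",
                entropy = "ent_dist", duration_ratio = "dur_ratio")
  adj <- comparisons[comparisons$type == "adjacent", , drop = FALSE]
  dis <- comparisons[comparisons$type == "distant", , drop = FALSE]
  if (nrow(adj) < 2L || nrow(dis) < 2L)
    ms_input_error("test_features: need >= 2 adjacent and >= 2 distant scores")
  ca <- alpha / n_tests_for_correction
  sem <- function(v) sd(v) / sqrt(length(v))
  rows <- lapply(names(features), function(fn) {
    col <- features[[fn]]
    x <- adj[[col]]
    y <- dis[[col]]
    w <- ms_welch(x, y)
    data.frame(feature = fn, mean_adjacent = mean(x), sem_adjacent = sem(x),
               mean_distant = mean(y), sem_distant = sem(y),
               t_statistic = w$t, p_value = w$p, corrected_alpha = ca,
               significant = w$p < ca)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
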