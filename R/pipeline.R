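#' Pipeline run configuration
#'
#' Exactly one of `audio` (a WAV path, optionally with `annotations`) or
#' `simulation` (a [song_spec()] or a list of its arguments) must be
#' supplied.
#'
#' @param audio path to a WAV recording, or `NULL`.
#' @param annotations optional phrase annotation file (label track or CSV).
#' @param simulation a [song_spec()] or a list of [song_spec()] arguments,
#'   or `NULL`.
#' @param amp_threshold,ent_threshold,min_dur_ms,min_gap_ms segmentation
#'   parameters (see [segment_syllables()]); set `amp_threshold = "auto"`
#'   to use [auto_thresholds()].
#' @param phrase_gap_ms phrase grouping gap (see [group_into_phrases()]).
#' @param k,exclusion distant-phrase sampling scheme (see [compare_song()]).
#' @param n_tests_for_correction Bonferroni family size.
#' @param seed integer seed for all randomness; recorded in every output.
#' @param out_dir output directory (created if missing).
#' @return An object of class `run_config`.
#' @export
run_config <- function(audio = NULL, annotations = NULL, simulation = NULL,
                       amp_threshold = 0.1, ent_threshold = -1.0,
                       min_dur_ms = 10L, min_gap_ms = 5L,
                       phrase_gap_ms = 250L, k = 10L, exclusion = 10L,
                       n_tests_for_correction = 4L, seed = 1L,
                       out_dir = "morphsong_out") {
  if (is.null(audio) == is.null(simulation))
    ms_input_error("run_config: exactly one of 'audio' or 'simulation' must be set")
  if (!is.null(simulation) && !inherits(simulation, "song_spec")) {
    if (!is.list(simulation))
      ms_input_error("run_config: 'simulation' must be a song_spec or argument list")
    if (is.null(simulation$seed)) simulation$seed <- seed
    simulation <- do.call(song_spec, simulation)
  }
  structure(list(audio = audio, annotations = annotations,
                 simulation = simulation, amp_threshold = amp_threshold,
                 ent_threshold = ent_threshold, min_dur_ms = min_dur_ms,
                 min_gap_ms = min_gap_ms, phrase_gap_ms = phrase_gap_ms,
                 k = k, exclusion = exclusion,
                 n_tests_for_correction = n_tests_for_correction,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The YAML file holds a flat mapping of [run_config()] arguments; a
#' `simulation` sub-mapping is passed to [song_spec()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ms_input_error("read_run_config: no such file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation) && !is.null(y$simulation$mode_probabilities))
    y$simulation$mode_probabilities <- unlist(y$simulation$mode_probabilities)
  if (!is.null(y$simulation) && !is.null(y$simulation$reps_range))
    y$simulation$reps_range <- as.integer(unlist(y$simulation$reps_range))
  do.call(run_config, y)
}

ms_write_log <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Runs feature extraction, segmentation, phrase grouping, the
#' adjacent-vs-distant comparison, the per-feature tests and the morphing
#' mode classification, writing all tables plus a parameter log into
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `segments`, `phrases`, `comparisons`, `stats`, `modes`,
#'   `mode_frequencies`) and `files` (all paths written).
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "run_config"))
    ms_input_error("run_analysis: config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$simulation)) {
      song <- generate_song(config$simulation)
      clip <- song$clip
    } else {
      clip <- load_audio(config$audio)
    }

    stage <- "features"
    ft <- song_features(clip)
    write_features_csv(ft, out("features.csv"))

    stage <- "segmentation"
    if (identical(config$amp_threshold, "auto")) {
      th <- auto_thresholds(ft$amp, ft$ent)
    } else {
      th <- list(amp_threshold = config$amp_threshold,
                 ent_threshold = config$ent_threshold)
    }
    segments <- segment_syllables(ft$amp, ft$ent, th$amp_threshold,
                                  th$ent_threshold, config$min_dur_ms,
                                  config$min_gap_ms)
    write_segments(segments, out("segments.csv"))
    syls <- extract_syllables(segments, ft$amp, ft$freq, ft$ent)

    stage <- "phrasing"
    if (!is.null(config$annotations)) {
      phrases <- assign_syllables_to_phrases(syls,
                                             read_annotations(config$annotations))
    } else {
      phrases <- group_into_phrases(syls, config$phrase_gap_ms)
    }
    write.csv(phrase_table(phrases), out("phrases.csv"), row.names = FALSE)

    stage <- "transition_stats"
    comparisons <- compare_song(phrases, k = config$k,
                                exclusion = config$exclusion,
                                seed = config$seed)
    write.csv(comparisons, out("distances.csv"), row.names = FALSE)
    stats <- test_features(comparisons, config$n_tests_for_correction)
    stats_out <- cbind(seed = config$seed, stats)
    write.csv(stats_out, out("feature_tests.csv"), row.names = FALSE)

    stage <- "mode_classifier"
    modes <- classify_song_transitions(phrases, comparisons)
    write.csv(modes, out("transition_modes.csv"), row.names = FALSE)
    freq <- mode_frequency_table(modes$mode)
    write.csv(freq, out("mode_frequencies.csv"), row.names = FALSE)

    stage <- "log"
    ms_write_log(c(
      "morphsong run_analysis",
      paste0("seed: ", config$seed),
      paste0("input: ", if (is.null(config$audio)) "simulation" else config$audio),
      paste0("amp_threshold: ", format(th$amp_threshold)),
      paste0("ent_threshold: ", format(th$ent_threshold)),
      paste0("min_dur_ms: ", config$min_dur_ms),
      paste0("min_gap_ms: ", config$min_gap_ms),
      paste0("phrase_gap_ms: ", config$phrase_gap_ms),
      paste0("k: ", config$k),
      paste0("exclusion: ", config$exclusion),
      paste0("n_tests_for_correction: ", config$n_tests_for_correction),
      paste0("n_syllables: ", length(syls)),
      paste0("n_phrases: ", length(phrases))), out("run_log.txt"))

    list(features = ft, segments = segments, phrases = phrases,
         comparisons = comparisons, stats = stats, modes = modes,
         mode_frequencies = freq,
         files = vapply(c("features.csv", "segments.csv", "phrases.csv",
                          "distances.csv", "feature_tests.csv",
                          "transition_modes.csv", "mode_frequencies.csv",
                          "run_log.txt"), out, character(1)))
  }, morphsong_input_error = function(e) {
    ms_input_error("run_analysis [stage: ", stage, "]: ", conditionMessage(e))
  })
  invisible(res)
}

#' Simulate a song and write its artifacts
#'
#' @param config a [run_config()] whose `simulation` field is set.
#' @param null_song generate a null song (independent phrase templates)?
#' @return Invisibly, the simulated song plus `files` written
#'   (WAV, ground-truth CSVs, spec JSON, log).
#' @export
run_simulate <- function(config, null_song = FALSE) {
  if (!inherits(config, "run_config"))
    ms_input_error("run_simulate: config must be a run_config")
  if (is.null(config$simulation))
    ms_input_error("run_simulate: config has no simulation spec")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  song <- if (null_song) generate_null_song(config$simulation)
          else generate_song(config$simulation)
  paths <- write_song(song, file.path(config$out_dir, "song"))
  log_path <- file.path(config$out_dir, "simulate_log.txt")
  ms_write_log(c("morphsong run_simulate",
                 paste0("seed: ", config$simulation$seed),
                 paste0("n_phrases: ", config$simulation$n_phrases),
                 paste0("null_song: ", null_song),
                 paste0("duration_ms: ", round(duration_ms(song$clip)))),
               log_path)
  song$files <- c(paths, log = log_path)
  invisible(song)
}
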