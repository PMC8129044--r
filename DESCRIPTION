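Package: morphsong
Title: Quantitative Analysis of Morphing Transitions in Mockingbird Song
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying acoustically gradual ("morphing")
    transitions between phrases in northern mockingbird song. Extracts
    per-millisecond acoustic feature contours (normalized amplitude envelope,
    mean frequency, Wiener entropy) from PCM WAV recordings, segments
    syllables with a dual amplitude/entropy threshold, groups syllables into
    phrases, computes dynamic-time-warping distances with a shared warping
    path across features, tests whether adjacent phrases are more similar
    than random distant phrases (Welch t-tests with Bonferroni correction),
    and classifies each transition into one of four morphing modes (pitch,
    timbre, stretch, squeeze) or contrast. A parametric synthetic-song
    generator with ground-truth transitions makes every stage testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
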