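# Independent oracles used to cross-check the package's implementations.

# Exhaustive DTW: minimum summed |a_i - b_j| over all admissible warping
# paths (steps (1,0), (0,1), (1,1)), by plain recursion on the grid.
brute_force_dtw_cost <- function(a, b) {
  n <- length(a); m <- length(b)
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    c <- abs(a[i] - b[j])
    v <- if (i == 1 && j == 1) c
         else {
           prev <- Inf
           if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
           if (i > 1) prev <- min(prev, rec(i - 1, j))
           if (j > 1) prev <- min(prev, rec(i, j - 1))
           c + prev
         }
    memo[i, j] <<- v
    v
  }
  rec(n, m)
}

# Direct windowed-RMS envelope: value at ms t (0-based) is the RMS of the
# samples within the window_ms window centred at (t + 0.5) ms, edge windows
# shifted inward to full length -- the stated definition, computed by loop.
direct_rms_envelope <- function(x, sr, window_ms = 10) {
  L <- max(1, round(window_ms * sr / 1000))
  n_ms <- floor(1000 * length(x) / sr)
  out <- numeric(n_ms)
  for (t in seq_len(n_ms)) {
    center <- round((t - 0.5) * sr / 1000)
    s <- center - L %/% 2 + 1
    s <- max(1, min(s, length(x) - L + 1))
    out[t] <- sqrt(mean(x[s:(s + L - 1)]^2))
  }
  out
}

# Textbook Welch t statistic for two samples
welch_t_oracle <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}

# Boundary F1 between detected and true segment tables at a ms tolerance
boundary_f1 <- function(detected, truth, tol = 5) {
  bd <- c(detected$onset_ms, detected$offset_ms)
  bt <- c(truth$onset_ms, truth$offset_ms)
  if (length(bd) == 0 || length(bt) == 0) return(0)
  near <- function(a, b) vapply(a, function(x) any(abs(b - x) <= tol), logical(1))
  prec <- mean(near(bd, bt))
  rec <- mean(near(bt, bd))
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
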