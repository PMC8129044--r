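test_that("DTW closed forms: identity and constant offset", {
  a <- c(0.1, 0.5, 0.3, 0.9, 0.2)
  d <- dtw_path(a, a)
  expect_equal(d$cost, 0)
  expect_equal(d$path, cbind(1:5, 1:5))

  d2 <- dtw_path(rep(0, 7), rep(0.4, 7))
  expect_equal(d2$cost, 7 * 0.4)
  expect_equal(d2$path, cbind(1:7, 1:7))

  expect_error(dtw_path(numeric(0), a), class = "morphsong_input_error")
})

test_that("DTW cost equals exhaustive path enumeration on random pairs", {
  set.seed(77)
  for (i in 1:60) {
    a <- sample(0:2, sample(1:6, 1), replace = TRUE)
    b <- sample(0:2, sample(1:6, 1), replace = TRUE)
    d <- dtw_path(a, b)
    expect_equal(d$cost, brute_force_dtw_cost(a, b))
    # path admissibility
    p <- d$path
    expect_equal(p[1, ], c(1L, 1L), ignore_attr = TRUE)
    expect_equal(p[nrow(p), ], c(length(a), length(b)), ignore_attr = TRUE)
    steps <- diff(p)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
    # the reported cost is attained by the reported path
    expect_equal(sum(abs(a[p[, 1]] - b[p[, 2]])), d$cost)
  }
})

test_that("warped_distance averages |diff| along the given path", {
  path <- cbind(c(1L, 2L, 2L, 3L), c(1L, 1L, 2L, 2L))
  expect_equal(warped_distance(path, c(0, 1, 2), c(0, 2)), 0.5)

  fa <- runif(4)
  expect_equal(warped_distance(cbind(1:4, 1:4), fa, fa), 0)
  expect_equal(warped_distance(cbind(1:4, 1:4), fa, fa + 0.3), 0.3)

  expect_error(warped_distance(path, c(0, 1), c(0, 2)),
               class = "morphsong_input_error")
})

test_that("duration ratio is symmetric, bounded and validated", {
  expect_equal(duration_ratio(100, 200), 0.5)
  expect_equal(duration_ratio(200, 100), 0.5)
  expect_equal(duration_ratio(130, 130), 1.0)
  expect_error(duration_ratio(0, 100), class = "morphsong_input_error")
  expect_error(duration_ratio(100, -5), class = "morphsong_input_error")
})

test_that("syllable distance: self-comparison and isolated feature offsets", {
  set.seed(12)
  s <- make_syll(runif(20), runif(20, 1000, 3000), -runif(20, 1, 4))
  d <- syllable_distance(s, s)
  expect_equal(c(d$amp_dist, d$freq_dist, d$ent_dist, d$dur_ratio),
               c(0, 0, 0, 1))

  # +500 Hz on the frequency contour only; diagonal path keeps the rest 0
  s2 <- make_syll(s$amp, s$freq + 500, s$ent)
  d2 <- syllable_distance(s, s2)
  expect_equal(c(d2$amp_dist, d2$freq_dist, d2$ent_dist, d2$dur_ratio),
               c(0, 500, 0, 1))
})

test_that("syllable distance matches a fully hand-computed example", {
  sa <- make_syll(c(0, 0.4, 0.8, 0.2), c(1000, 1200, 1400, 1300),
                  c(-3, -2.5, -2, -2.2))
  sb <- make_syll(c(0, 0.8, 0.1), c(900, 1500, 1200), c(-3.2, -1.8, -2.4))
  # DTW grid worked by hand: optimal cost 0.5 via (1,1),(2,1),(3,2),(4,3)
  d <- dtw_path(sa$amp, sb$amp)
  expect_equal(d$cost, 0.5)
  expect_equal(d$path, cbind(c(1L, 2L, 3L, 4L), c(1L, 1L, 2L, 3L)))
  pd <- syllable_distance(sa, sb)
  expect_equal(pd$amp_dist, 0.125)
  expect_equal(pd$freq_dist, 150)
  expect_equal(pd$ent_dist, 0.325)
  expect_equal(pd$dur_ratio, 0.75)
})

test_that("fused kernel agrees with the stepwise path-transfer route", {
  set.seed(13)
  for (i in 1:20) {
    la <- sample(3:30, 1)
    sa <- make_syll(runif(la), runif(la, 500, 5000), -runif(la, 0, 5))
    lb <- sample(3:30, 1)
    sb <- make_syll(runif(lb), runif(lb, 500, 5000), -runif(lb, 0, 5))
    d <- dtw_path(sa$amp, sb$amp)
    pd <- syllable_distance(sa, sb)
    expect_equal(pd$amp_dist, warped_distance(d$path, sa$amp, sb$amp))
    expect_equal(pd$freq_dist, warped_distance(d$path, sa$freq, sb$freq))
    expect_equal(pd$ent_dist, warped_distance(d$path, sa$ent, sb$ent))
  }
})

test_that("distances are symmetric, finite and non-negative", {
  set.seed(14)
  for (i in 1:15) {
    la <- sample(5:40, 1); lb <- sample(5:40, 1)
    sa <- make_syll(runif(la), runif(la, 500, 5000), -runif(la, 0, 5))
    sb <- make_syll(runif(lb), runif(lb, 500, 5000), -runif(lb, 0, 5))
    ab <- syllable_distance(sa, sb)
    ba <- syllable_distance(sb, sa)
    vals <- c(ab$amp_dist, ab$freq_dist, ab$ent_dist, ab$dur_ratio)
    expect_true(all(is.finite(vals)) && all(vals[1:3] >= 0))
    expect_equal(vals, c(ba$amp_dist, ba$freq_dist, ba$ent_dist, ba$dur_ratio))
  }
})

test_that("phrase distance averages all m x n syllable comparisons", {
  set.seed(15)
  mk <- function(n) lapply(seq_len(n), function(i) {
    l <- sample(5:15, 1)
    make_syll(runif(l), runif(l, 1000, 4000), -runif(l, 0, 4))
  })
  pa <- phrase(1, mk(4)); pb <- phrase(2, mk(5))
  pd <- phrase_distance(pa, pb)
  expect_equal(pd$n_comparisons, 20L)

  # identical single-syllable phrases
  s <- mk(1)
  pd1 <- phrase_distance(phrase(1, s), phrase(2, s))
  expect_equal(c(pd1$amp_dist, pd1$freq_dist, pd1$ent_dist, pd1$dur_ratio),
               c(0, 0, 0, 1))
  expect_equal(pd1$n_comparisons, 1L)

  # 2x2 phrases against the field-wise mean of component distances
  pa2 <- phrase(1, mk(2)); pb2 <- phrase(2, mk(2))
  pd2 <- phrase_distance(pa2, pb2)
  parts <- sapply(1:2, function(i) sapply(1:2, function(j) {
    d <- syllable_distance(pa2$syllables[[i]], pb2$syllables[[j]])
    c(d$amp_dist, d$freq_dist, d$ent_dist, d$dur_ratio)
  }), simplify = "array")
  mu <- apply(parts, 1, mean)
  expect_equal(c(pd2$amp_dist, pd2$freq_dist, pd2$ent_dist, pd2$dur_ratio),
               unname(mu))

  # symmetry at the phrase level
  pd2r <- phrase_distance(pb2, pa2)
  expect_equal(pd2$amp_dist, pd2r$amp_dist)
  expect_equal(pd2$dur_ratio, pd2r$dur_ratio)
})
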