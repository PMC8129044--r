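#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with absolute-difference cost and the symmetric
// step set {(1,0),(0,1),(1,1)}, no window constraint. Backtracking breaks
// ties deterministically: diagonal first, then vertical, then horizontal.
// Returns the optimal path (1-based index pairs) and its total cost.
// [[Rcpp::export(name = ".dtw_path_cpp")]]
List dtw_path_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n < 1 || m < 1) stop("dtw_path: empty sequence");

  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(a[i] - b[j]);
      if (i == 0 && j == 0) D(i, j) = c;
      else {
        double best = R_PosInf;
        if (i > 0 && j > 0) best = D(i - 1, j - 1);
        if (i > 0 && D(i - 1, j) < best) best = D(i - 1, j);
        if (j > 0 && D(i, j - 1) < best) best = D(i, j - 1);
        D(i, j) = c + best;
      }
    }
  }

  // backtrack (ties: diagonal > vertical > horizontal)
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double d = D(i - 1, j - 1), v = D(i - 1, j), h = D(i, j - 1);
      if (d <= v && d <= h) { --i; --j; }
      else if (v <= h) { --i; }
      else { --j; }
    }
    pi.push_back(i); pj.push_back(j);
  }

  const int len = pi.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {          // reverse to start at (1,1)
    path(k, 0) = pi[len - 1 - k] + 1;
    path(k, 1) = pj[len - 1 - k] + 1;
  }
  return List::create(_["path"] = path, _["cost"] = D(n - 1, m - 1));
}

// Fused kernel for syllable comparison: DTW on the amplitude envelopes,
// then mean |diff| along that single path for amplitude, frequency and
// entropy contours, without materialising the path in R. Same alignment,
// costs and tie-breaking as dtw_path_cpp.
// [[Rcpp::export(name = ".syllable_dist4_cpp")]]
NumericVector syllable_dist4_cpp(NumericVector ampA, NumericVector ampB,
                                 NumericVector freqA, NumericVector freqB,
                                 NumericVector entA, NumericVector entB) {
  const int n = ampA.size(), m = ampB.size();
  if (n < 1 || m < 1) stop("syllable_dist4: empty contour");
  if (freqA.size() != n || entA.size() != n ||
      freqB.size() != m || entB.size() != m)
    stop("syllable_dist4: contour lengths differ within a syllable");

  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(ampA[i] - ampB[j]);
      if (i == 0 && j == 0) D(i, j) = c;
      else {
        double best = R_PosInf;
        if (i > 0 && j > 0) best = D(i - 1, j - 1);
        if (i > 0 && D(i - 1, j) < best) best = D(i - 1, j);
        if (j > 0 && D(i, j - 1) < best) best = D(i, j - 1);
        D(i, j) = c + best;
      }
    }
  }

  int i = n - 1, j = m - 1, len = 0;
  double sa = 0, sf = 0, se = 0;
  for (;;) {
    sa += std::abs(ampA[i] - ampB[j]);
    sf += std::abs(freqA[i] - freqB[j]);
    se += std::abs(entA[i] - entB[j]);
    ++len;
    if (i == 0 && j == 0) break;
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double d = D(i - 1, j - 1), v = D(i - 1, j), h = D(i, j - 1);
      if (d <= v && d <= h) { --i; --j; }
      else if (v <= h) { --i; }
      else { --j; }
    }
  }
  return NumericVector::create(sa / len, sf / len, se / len, (double)len);
}
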