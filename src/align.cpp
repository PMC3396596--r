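#include <Rcpp.h>
using namespace Rcpp;

// Gotoh three-state global alignment over a precomputed column-score matrix.
// S(i, j) scores pairing row-unit i of "a" with column-unit j of "b" (units are
// residues for sequence-sequence alignment, profile columns for
// profile-profile alignment). gap_open is charged for the first gapped unit,
// gap_extend for each further one. Tie-break in traceback: diagonal first,
// then gap in a (consuming b), then gap in b (consuming a).
// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;
  // state 0 = M (diagonal), 1 = Y (gap in a, consumes b), 2 = X (gap in b)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = -gap_open - (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = -gap_open - (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M[at(i - 1, j - 1)];
      if (Y[at(i - 1, j - 1)] > best) best = Y[at(i - 1, j - 1)];
      if (X[at(i - 1, j - 1)] > best) best = X[at(i - 1, j - 1)];
      M[at(i, j)] = best + S(i - 1, j - 1);
      double yo = M[at(i, j - 1)] - gap_open;
      double ye = Y[at(i, j - 1)] - gap_extend;
      Y[at(i, j)] = yo >= ye ? yo : ye;
      double xo = M[at(i - 1, j)] - gap_open;
      double xe = X[at(i - 1, j)] - gap_extend;
      X[at(i, j)] = xo >= xe ? xo : xe;
    }
  }
  // final state: prefer M, then Y, then X on ties
  double score = M[at(n, m)];
  int state = 0;
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 1; }
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 2; }
  // traceback
  std::vector<int> ai, bi;  // 1-based unit index or 0 for gap
  int i = n, j = m;
  const double EPS = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error");
      ai.push_back(i); bi.push_back(j);
      double prev = M[at(i, j)] - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M[at(i, j)] - prev) < EPS) state = 0;
      else if (std::abs(Y[at(i, j)] - prev) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {  // gap in a: consume b[j]
      ai.push_back(0); bi.push_back(j);
      double cur = Y[at(i, j)];
      --j;
      if (i == 0) { state = (j == 0) ? 0 : 1; continue; }
      if (std::abs(M[at(i, j)] - gap_open - cur) < EPS) state = 0;
      else state = 1;
    } else {  // gap in b: consume a[i]
      ai.push_back(i); bi.push_back(0);
      double cur = X[at(i, j)];
      --i;
      if (j == 0) { state = (i == 0) ? 0 : 2; continue; }
      if (std::abs(M[at(i, j)] - gap_open - cur) < EPS) state = 0;
      else state = 2;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}

// Window scores of an ungapped PSSM scan. seq: 0-based residue indices,
// -1 for unknown (scores 0 at every column). logodds: L x A matrix.
// Full windows plus terminal windows overlapping by at least min_cols.
// Returns one row per window: start, end (1-based, clipped), n_cols scored,
// truncated flag, score.
// [[Rcpp::export]]
DataFrame pssm_window_scores_cpp(IntegerVector seq, NumericMatrix logodds,
                                 int min_cols) {
  const int n = seq.size(), L = logodds.nrow();
  std::vector<int> starts, ends, ncols;
  std::vector<bool> trunc;
  std::vector<double> scores;
  for (int s = 1 - (L - min_cols); s <= n - min_cols + 1; ++s) {
    int lo = std::max(1, s), hi = std::min(n, s + L - 1);
    int k = hi - lo + 1;
    if (k < min_cols) continue;
    double sc = 0.0;
    for (int p = lo; p <= hi; ++p) {
      int col = p - s;           // profile column, 0-based
      int r = seq[p - 1];
      if (r >= 0) sc += logodds(col, r);
    }
    starts.push_back(lo);
    ends.push_back(hi);
    ncols.push_back(k);
    trunc.push_back(k < L);
    scores.push_back(sc);
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["n_cols"] = ncols, _["truncated"] = trunc,
                           _["score"] = scores);
}
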