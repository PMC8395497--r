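#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties and unpenalized end
// gaps (EMBOSS Needle default "endweight" off).  A gap of length L costs
// gap_open + (L - 1) * gap_extend.  Sequences arrive integer-encoded
// (1-based row/column indices into the substitution matrix); the traceback
// is deterministic: at equal score the diagonal (match) state is preferred
// over a gap in the reference ("up", query residue vs gap), which is
// preferred over a gap in the query ("left").

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".needle_align")]]
List needle_align(IntegerVector q, IntegerVector r, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = q.size(), m = r.size();
  // state 0 = M (diagonal), 1 = X (gap in reference, consumes query),
  // 2 = Y (gap in query, consumes reference)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = 0.0;  // free leading gap in ref
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = 0.0;  // free leading gap in query

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(q[i - 1] - 1, r[j - 1] - 1);
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      M[at(i, j)] = s + std::max(dM, std::max(dX, dY));
      X[at(i, j)] = std::max(M[at(i - 1, j)] - gap_open,
                    std::max(X[at(i - 1, j)] - gap_extend,
                             Y[at(i - 1, j)] - gap_open));
      Y[at(i, j)] = std::max(M[at(i, j - 1)] - gap_open,
                    std::max(X[at(i, j - 1)] - gap_open,
                             Y[at(i, j - 1)] - gap_extend));
    }
  }

  // End gaps are free: the optimum ends anywhere on the last row or column;
  // the remainder of the other sequence is appended against gaps at no
  // cost.  Preference order on ties: the corner first, then cells of the
  // last column from high i down, then cells of the last row from high j
  // down; within a cell M > X > Y.
  double best = NEG_INF;
  int bi = n, bj = m, bs = 0;
  auto consider = [&](int i, int j) {
    double v[3] = {M[at(i, j)], X[at(i, j)], Y[at(i, j)]};
    for (int s = 0; s < 3; ++s)
      if (v[s] > best) { best = v[s]; bi = i; bj = j; bs = s; }
  };
  consider(n, m);
  for (int i = n - 1; i >= 0; --i) consider(i, m);
  for (int j = m - 1; j >= 0; --j) consider(n, j);

  // emit trailing free end gaps
  std::vector<int> oq, orf;  // integer-encoded emitted columns (0 = gap)
  for (int i = n; i > bi; --i) { oq.push_back(q[i - 1]); orf.push_back(0); }
  for (int j = m; j > bj; --j) { oq.push_back(0); orf.push_back(r[j - 1]); }

  int i = bi, j = bj, st = bs;
  while (i > 0 || j > 0) {
    if (st == 0) {  // M
      if (i == 0 && j == 0) break;
      if (i == 0) { st = 2; continue; }
      if (j == 0) { st = 1; continue; }
      oq.push_back(q[i - 1]); orf.push_back(r[j - 1]);
      double tgt = M[at(i, j)] - sub(q[i - 1] - 1, r[j - 1] - 1);
      --i; --j;
      if (M[at(i, j)] >= tgt - 1e-9 && M[at(i, j)] >= X[at(i, j)] &&
          M[at(i, j)] >= Y[at(i, j)]) st = 0;
      else if (X[at(i, j)] >= Y[at(i, j)]) st = 1;
      else st = 2;
      if (i == 0 && j == 0) break;
    } else if (st == 1) {  // X: query residue vs gap
      if (i == 0) { st = 2; continue; }
      oq.push_back(q[i - 1]); orf.push_back(0);
      double cur = X[at(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (i == 0) { // remaining is a free leading gap run; stay in X (free)
        st = 1;
        // leading X cells are 0-initialized; continue popping
        continue;
      }
      if (j == 0) { st = 1; continue; }
      if (M[at(i, j)] - gap_open >= cur - 1e-9) st = 0;
      else if (X[at(i, j)] - gap_extend >= cur - 1e-9) st = 1;
      else st = 2;
    } else {  // Y: gap vs reference residue
      if (j == 0) { st = 1; continue; }
      oq.push_back(0); orf.push_back(r[j - 1]);
      double cur = Y[at(i, j)];
      --j;
      if (i == 0 && j == 0) break;
      if (j == 0) { st = 2; continue; }
      if (i == 0) { st = 2; continue; }
      if (M[at(i, j)] - gap_open >= cur - 1e-9) st = 0;
      else if (X[at(i, j)] - gap_open >= cur - 1e-9) st = 1;
      else st = 2;
    }
  }

  IntegerVector aligned_q(oq.size()), aligned_r(orf.size());
  int L = oq.size();
  for (int k = 0; k < L; ++k) {
    aligned_q[k] = oq[L - 1 - k];
    aligned_r[k] = orf[L - 1 - k];
  }
  return List::create(_["q"] = aligned_q, _["r"] = aligned_r,
                      _["score"] = best);
}
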