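#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment (three-state Gotoh recurrence) with
// traceback. Gap of length L costs open + (L-1)*ext; end gaps are
// penalized like internal ones. Substitution scores follow the EDNAFULL
// core: +5 identical base, -4 otherwise, with N scoring 0 against
// everything. Returns the optimal score plus the fraction of alignment
// columns whose substitution score is positive (the EMBOSS-style
// "similarity" percentage as a fraction).

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const double NEG = -std::numeric_limits<double>::infinity();
  // state 0 = M (diagonal), 1 = X (gap in b, consume a), 2 = Y (gap in a)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> X(M), Y(M);
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = -gap_open - (i - 1) * gap_ext;
  for (int j = 1; j <= m; ++j) Y[0][j] = -gap_open - (j - 1) * gap_ext;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subscore(a[i - 1], b[j - 1], match, mismatch);
      double dM = M[i - 1][j - 1], dX = X[i - 1][j - 1], dY = Y[i - 1][j - 1];
      M[i][j] = s + std::max(dM, std::max(dX, dY));
      X[i][j] = std::max(M[i - 1][j] - gap_open,
                std::max(X[i - 1][j] - gap_ext, Y[i - 1][j] - gap_open));
      Y[i][j] = std::max(M[i][j - 1] - gap_open,
                std::max(Y[i][j - 1] - gap_ext, X[i][j - 1] - gap_open));
    }
  }
  double best = std::max(M[n][m], std::max(X[n][m], Y[n][m]));
  int state = (best == M[n][m]) ? 0 : (best == X[n][m] ? 1 : 2);
  // traceback; prefer M over X over Y at score ties for determinism
  int i = n, j = m, positives = 0, len = 0;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    ++len;
    if (state == 0) {
      double s = subscore(a[i - 1], b[j - 1], match, mismatch);
      if (s > 0) ++positives;
      double target = M[i][j] - s;
      if (std::abs(M[i - 1][j - 1] - target) < eps) state = 0;
      else if (std::abs(X[i - 1][j - 1] - target) < eps) state = 1;
      else state = 2;
      --i; --j;
      if (i == 0 && j == 0) break;
    } else if (state == 1) {
      double cur = X[i][j];
      if (std::abs(M[i - 1][j] - gap_open - cur) < eps) state = 0;
      else if (std::abs(X[i - 1][j] - gap_ext - cur) < eps) state = 1;
      else state = 2;
      --i;
      if (i == 0 && j == 0) break;
      if (i == 0 && state != 2) state = 2;  // only left-gaps remain
    } else {
      double cur = Y[i][j];
      if (std::abs(M[i][j - 1] - gap_open - cur) < eps) state = 0;
      else if (std::abs(Y[i][j - 1] - gap_ext - cur) < eps) state = 2;
      else state = 1;
      --j;
      if (i == 0 && j == 0) break;
      if (j == 0 && state != 1) state = 1;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  return List::create(_["score"] = best,
                      _["length"] = len,
                      _["positives"] = positives,
                      _["similarity"] = (double)positives / (double)len);
}
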