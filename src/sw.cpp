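#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps. A gap of length L costs
// open + ext * L (BLAST convention). Sequences arrive as 1-based integer
// codes into the substitution matrix S; code 0 means "unknown residue" and
// scores 0 against everything.

static inline double subscore(const NumericMatrix& S, int a, int b) {
  if (a == 0 || b == 0) return 0.0;
  return S(a - 1, b - 1);
}

// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double open, double ext) {
  const int n = a.size(), m = b.size();
  const double ninf = -1e30, gi = open + ext;
  std::vector<double> H(m + 1, 0.0), E(m + 1, ninf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;        // H[i-1][j-1]
    double F = ninf, Hj = 0.0; // H[i][0] = 0
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - ext, H[j] - gi);   // vertical: consume a_i
      F = std::max(F - ext, Hj - gi);           // horizontal: consume b_j
      double h = diag + subscore(S, a[i - 1], b[j - 1]);
      h = std::max(std::max(h, E[j]), std::max(F, 0.0));
      diag = H[j];
      H[j] = Hj = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Full DP with traceback; returns alignment statistics needed for family
// assignment (identity over aligned columns, query coverage).
// [[Rcpp::export]]
List sw_stats_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double open, double ext) {
  const int n = a.size(), m = b.size();
  const double ninf = -1e30, gi = open + ext;
  const int W = m + 1;
  std::vector<double> H((n + 1) * W, 0.0), E((n + 1) * W, ninf),
      F((n + 1) * W, ninf);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(E[(i - 1) * W + j] - ext, H[(i - 1) * W + j] - gi);
      double f = std::max(F[i * W + j - 1] - ext, H[i * W + j - 1] - gi);
      double h = H[(i - 1) * W + j - 1] + subscore(S, a[i - 1], b[j - 1]);
      h = std::max(std::max(h, e), std::max(f, 0.0));
      E[i * W + j] = e;
      F[i * W + j] = f;
      H[i * W + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int aligned = 0, matches = 0;
  int qend = bi, qstart = bi + 1, send = bj, sstart = bj + 1;
  // traceback from (bi, bj) in state H until the score hits 0
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E (vertical), 2 = F (horizontal)
  const double tol = 1e-9;
  while (i > 0 && j > 0) {
    double cur = (state == 0) ? H[i * W + j]
               : (state == 1) ? E[i * W + j] : F[i * W + j];
    if (state == 0) {
      if (cur <= tol) break;
      double d = H[(i - 1) * W + j - 1] + subscore(S, a[i - 1], b[j - 1]);
      if (std::abs(cur - d) < tol) {
        ++aligned;
        if (a[i - 1] != 0 && a[i - 1] == b[j - 1]) ++matches;
        qstart = i; sstart = j;
        --i; --j;
      } else if (std::abs(cur - E[i * W + j]) < tol) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      bool fromH = std::abs(cur - (H[(i - 1) * W + j] - gi)) < tol;
      --i;
      if (fromH) state = 0;
    } else {
      bool fromH = std::abs(cur - (H[i * W + j - 1] - gi)) < tol;
      --j;
      if (fromH) state = 0;
    }
  }
  if (best <= 0.0) { qstart = qend = sstart = send = 0; }
  return List::create(_["score"] = best, _["aligned_pairs"] = aligned,
                      _["matches"] = matches, _["query_start"] = qstart,
                      _["query_end"] = qend, _["subject_start"] = sstart,
                      _["subject_end"] = send);
}
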