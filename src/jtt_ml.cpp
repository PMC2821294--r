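#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximum-likelihood pairwise distance under a reversible empirical model.
// The per-pair sufficient statistic is the 20x20 matrix of aligned residue
// counts N over pairwise-complete columns; the log-likelihood at branch
// length t is sum_ab N_ab * log(pi_a * P_t(a,b)), with P_t reconstructed
// from the eigendecomposition passed in from R.

static double pair_loglik(const std::vector<double>& N,
                          const NumericMatrix& V, const NumericMatrix& Vinv,
                          const NumericVector& lambda,
                          const NumericVector& pi, double t) {
  double el[20];
  for (int k = 0; k < 20; ++k) el[k] = std::exp(lambda[k] * t);
  double ll = 0.0;
  for (int a = 0; a < 20; ++a) {
    for (int b = 0; b < 20; ++b) {
      double nab = N[a * 20 + b];
      if (nab == 0.0) continue;
      double p = 0.0;
      for (int k = 0; k < 20; ++k) p += V(a, k) * el[k] * Vinv(k, b);
      if (p < 1e-300) p = 1e-300;
      ll += nab * std::log(pi[a] * p);
    }
  }
  return ll;
}

static double golden_max(const std::vector<double>& N,
                         const NumericMatrix& V, const NumericMatrix& Vinv,
                         const NumericVector& lambda, const NumericVector& pi,
                         double lo, double hi, double tol) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = pair_loglik(N, V, Vinv, lambda, pi, x1);
  double f2 = pair_loglik(N, V, Vinv, lambda, pi, x2);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = pair_loglik(N, V, Vinv, lambda, pi, x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = pair_loglik(N, V, Vinv, lambda, pi, x1);
    }
  }
  double mid = (a + b) / 2.0;
  // compare the interior optimum against the interval ends (the likelihood
  // can be monotone, e.g. identical sequences or saturation)
  double fm = pair_loglik(N, V, Vinv, lambda, pi, mid);
  double fl = pair_loglik(N, V, Vinv, lambda, pi, lo);
  double fh = pair_loglik(N, V, Vinv, lambda, pi, hi);
  if (fl >= fm && fl >= fh) return lo;
  if (fh >= fm && fh >= fl) return hi;
  return mid;
}

// aln: taxa x columns integer matrix, codes 1..20, 0 = gap/unknown.
// Returns the full symmetric matrix of ML distances.
// [[Rcpp::export]]
NumericMatrix jtt_ml_distmat_cpp(IntegerMatrix aln, NumericMatrix V,
                                 NumericMatrix Vinv, NumericVector lambda,
                                 NumericVector pi, double lower, double upper,
                                 double tol) {
  const int ntax = aln.nrow(), ncol = aln.ncol();
  NumericMatrix D(ntax, ntax);
  std::vector<double> N(400);
  for (int i = 0; i < ntax; ++i) {
    for (int j = i + 1; j < ntax; ++j) {
      std::fill(N.begin(), N.end(), 0.0);
      int shared = 0;
      for (int c = 0; c < ncol; ++c) {
        int a = aln(i, c), b = aln(j, c);
        if (a > 0 && b > 0) { N[(a - 1) * 20 + (b - 1)] += 1.0; ++shared; }
      }
      if (shared == 0)
        stop("no shared non-gap columns between rows %d and %d", i + 1, j + 1);
      double t = golden_max(N, V, Vinv, lambda, pi, lower, upper, tol);
      D(i, j) = D(j, i) = t;
    }
  }
  return D;
}
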