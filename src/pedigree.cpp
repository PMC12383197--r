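#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Pedigree algebra. Animals are coded 1..n in an order where every parent
// precedes its offspring; 0 marks an unknown parent.

// Tabular (recursive) numerator relationship matrix. Dense; intended for
// moderate pedigrees (tests, genotyped subsets).

// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(const IntegerVector& sire, const IntegerVector& dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1;
    const int d = dam[i] - 1;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s >= 0) a += 0.5 * A(j, s);
      if (d >= 0) a += 0.5 * A(j, d);
      A(i, j) = a;
      A(j, i) = a;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

// Inbreeding coefficients for every animal, F_i = A(s_i, d_i) / 2.
//
// Computed exactly without a dense A: each required A(s, d) is read off a
// full column A[, s] obtained by Colleau's indirect method
// (A v = T D T' v with the usual gene-flow T and Mendelian-sampling D).
// Columns are cached per sire, since consecutive offspring share sires.
// The backward sweep for column s only touches ancestors of s, whose F
// values are already known when animal i > s is processed, so every cached
// column is exact.

// [[Rcpp::export]]
NumericVector cpp_inbreeding(const IntegerVector& sire, const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n);
  std::map<int, std::vector<double> > cache;
  const size_t cache_max = 600;

  std::vector<double> y(n), u(n);

  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1;
    const int d = dam[i] - 1;
    // Mendelian sampling variance for animal i (F of an unknown parent
    // enters as -1, the standard convention).
    const double Fs = (s >= 0) ? F[s] : -1.0;
    const double Fd = (d >= 0) ? F[d] : -1.0;
    D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s < 0 || d < 0) {
      F[i] = 0.0;
      continue;
    }
    std::map<int, std::vector<double> >::iterator it = cache.find(s);
    if (it == cache.end()) {
      // Backward sweep: y = (I - P')^{-1} e_s, nonzero only on anc(s).
      std::fill(y.begin(), y.begin() + (s + 1), 0.0);
      y[s] = 1.0;
      for (int k = s; k >= 0; --k) {
        const double yk = y[k];
        if (yk == 0.0) continue;
        const int ks = sire[k] - 1;
        const int kd = dam[k] - 1;
        if (ks >= 0) y[ks] += 0.5 * yk;
        if (kd >= 0) y[kd] += 0.5 * yk;
      }
      // Scale by D, forward sweep: u = (I - P)^{-1} (D y).
      for (int k = 0; k < n; ++k) u[k] = (k <= s) ? D[k] * y[k] : 0.0;
      for (int k = 0; k < n; ++k) {
        const int ks = sire[k] - 1;
        const int kd = dam[k] - 1;
        double add = 0.0;
        if (ks >= 0) add += 0.5 * u[ks];
        if (kd >= 0) add += 0.5 * u[kd];
        u[k] += add;
      }
      if (cache.size() >= cache_max) cache.clear();
      it = cache.insert(std::make_pair(s, std::vector<double>(u.begin(), u.end()))).first;
    }
    F[i] = 0.5 * it->second[d];
  }
  return F;
}
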