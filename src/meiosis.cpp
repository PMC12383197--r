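#include <Rcpp.h>
#include <algorithm>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Gamete sampling for a loci-major haplotype store.
//
// `haplo` has one row per locus and two adjacent columns per individual
// (columns 2i-1, 2i hold the two haplotypes of individual i, 1-based).
// For each requested gamete, crossovers per chromosome are Poisson with
// mean equal to the map length in Morgans, breakpoints are uniform on the
// chromosome, and the starting haplotype is a fair coin. Recurrent
// mutation then flips each locus independently with probability
// `mut_rate` (drawn as a binomial count plus a uniform choice of distinct
// loci, which is the same process).
//
// Uses R's RNG throughout so results are governed by set.seed().

// [[Rcpp::export]]
IntegerMatrix cpp_make_gametes(const IntegerMatrix& haplo,
                               const IntegerVector& parent,
                               const NumericVector& pos,
                               const IntegerVector& chrom_first,
                               const IntegerVector& chrom_nloci,
                               const NumericVector& chrom_cM,
                               double mut_rate) {
  const int L = haplo.nrow();
  const int n = parent.size();
  const int C = chrom_cM.size();
  IntegerMatrix out(L, n);
  std::vector<double> bp;
  bp.reserve(8);

  for (int g = 0; g < n; ++g) {
    const int p = parent[g] - 1;
    const int c1 = 2 * p;
    const int c2 = 2 * p + 1;
    for (int c = 0; c < C; ++c) {
      const int s = chrom_first[c] - 1;
      const int m = chrom_nloci[c];
      const double len = chrom_cM[c];
      const int k = (int) R::rpois(len / 100.0);
      bp.clear();
      for (int j = 0; j < k; ++j) bp.push_back(unif_rand() * len);
      std::sort(bp.begin(), bp.end());
      int cur = (unif_rand() < 0.5) ? c1 : c2;
      size_t bi = 0;
      for (int j = 0; j < m; ++j) {
        const double x = pos[s + j];
        while (bi < bp.size() && bp[bi] <= x) {
          cur = (cur == c1) ? c2 : c1;
          ++bi;
        }
        out(s + j, g) = haplo(s + j, cur);
      }
    }
    if (mut_rate > 0.0) {
      int nm = (int) R::rbinom((double) L, mut_rate);
      if (nm > 0) {
        std::unordered_set<int> hit;
        while ((int) hit.size() < nm) {
          int j = (int) (unif_rand() * L);
          if (j >= L) j = L - 1;
          hit.insert(j);
        }
        for (int j : hit) out(j, g) = 1 - out(j, g);
      }
    }
  }
  return out;
}
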