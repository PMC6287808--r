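#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Form one gamete from a parent's two haplotypes (rows r1, r2 of H, 0-based).
// Crossover count ~ Poisson(len/100) with uniformly placed break points
// (Haldane model, no interference); the starting haplotype is chosen at random.
static void form_gamete(const IntegerMatrix& H, int r1, int r2,
                        const NumericVector& pos, double len,
                        IntegerMatrix& out, int orow) {
  const int L = H.ncol();
  int ncx = (int) R::rpois(len / 100.0);
  int cur = (unif_rand() < 0.5) ? r1 : r2;
  if (ncx == 0) {
    for (int j = 0; j < L; ++j) out(orow, j) = H(cur, j);
    return;
  }
  std::vector<double> cx((size_t) ncx);
  for (int k = 0; k < ncx; ++k) cx[k] = unif_rand() * len;
  std::sort(cx.begin(), cx.end());
  int k = 0;
  for (int j = 0; j < L; ++j) {
    while (k < ncx && cx[k] < pos[j]) {
      cur = (cur == r1) ? r2 : r1;
      ++k;
    }
    out(orow, j) = H(cur, j);
  }
}

// Drop one generation of gametes. H holds parental haplotypes, two rows per
// individual (individual k, 1-based, occupies rows 2k-1 and 2k). dam/sire are
// 1-based individual indices, one entry per offspring. Rows 2i-1 / 2i of the
// result are the maternal / paternal gametes of offspring i. Recurrent
// mutation flips alleles at rate mut_rate per locus per gamete.
// [[Rcpp::export]]
IntegerMatrix drop_gametes_cpp(IntegerMatrix H, NumericVector pos,
                               IntegerVector dam, IntegerVector sire,
                               double chrom_len, double mut_rate) {
  const int n = dam.size();
  const int L = H.ncol();
  IntegerMatrix out(2 * n, L);
  for (int i = 0; i < n; ++i) {
    int d = dam[i] - 1, s = sire[i] - 1;
    form_gamete(H, 2 * d, 2 * d + 1, pos, chrom_len, out, 2 * i);
    form_gamete(H, 2 * s, 2 * s + 1, pos, chrom_len, out, 2 * i + 1);
    if (mut_rate > 0) {
      for (int g = 0; g < 2; ++g) {
        int nm = (int) R::rbinom((double) L, mut_rate);
        for (int m = 0; m < nm; ++m) {
          int j = (int) (unif_rand() * L);
          if (j >= L) j = L - 1;
          out(2 * i + g, j) = 1 - out(2 * i + g, j);
        }
      }
    }
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Single gamete from a haplotype pair; exposed for the recombination API.
// [[Rcpp::export]]
IntegerVector recombine_cpp(IntegerVector hap1, IntegerVector hap2,
                            NumericVector pos, double chrom_len) {
  IntegerMatrix H(2, hap1.size());
  for (int j = 0; j < hap1.size(); ++j) {
    H(0, j) = hap1[j];
    H(1, j) = hap2[j];
  }
  IntegerMatrix out(1, hap1.size());
  form_gamete(H, 0, 1, pos, chrom_len, out, 0);
  return out.row(0);
}
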