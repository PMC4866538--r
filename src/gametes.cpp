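// Gamete formation for the Wright-Fisher simulator. Crossovers follow the
// Haldane model: per-interval switch probabilities r are converted back to
// map distances and crossover points are realized as a unit-rate Poisson
// process along the map, which costs O(crossovers) random draws per gamete
// instead of O(loci). Intervals with r = 0.5 (independent assortment,
// e.g. arm boundaries) restart the process with a fresh random bit drawn
// from a 30-bit pool. Uses R's RNG throughout, so results are reproducible
// under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {
struct BitPool {
  unsigned int pool = 0;
  int left = 0;
  int next() {
    if (left == 0) {
      pool = (unsigned int)(unif_rand() * 1073741824.0); // 30 bits
      left = 30;
    }
    int b = pool & 1u;
    pool >>= 1;
    --left;
    return b;
  }
};
}

// `haps` is loci x chromosomes (chromosomes 2i-1, 2i belong to diploid i),
// so the per-gamete locus walk is contiguous in memory; returns loci x n.
// [[Rcpp::export(name = ".make_gametes_cpp")]]
IntegerMatrix make_gametes_cpp(const IntegerMatrix &haps,
                               const IntegerVector &parents,
                               const NumericVector &rfrac) {
  int n = parents.size();
  int L = haps.nrow();
  IntegerMatrix out(L, n);
  RNGScope scope;
  BitPool bits;

  // interval classes: 0 = no recombination, 1 = free, 2 = linked (map d)
  std::vector<int> type(L > 1 ? L - 1 : 0);
  std::vector<double> mapd(L > 1 ? L - 1 : 0);
  for (int j = 0; j + 1 < L; ++j) {
    double r = rfrac[j];
    if (r <= 0) {
      type[j] = 0;
    } else if (r >= 0.5) {
      type[j] = 1;
    } else {
      type[j] = 2;
      mapd[j] = -0.5 * std::log1p(-2.0 * r); // inverse Haldane
    }
  }

  const int *hp = haps.begin();
  int *op = out.begin();
  for (int i = 0; i < n; ++i) {
    int base = 2 * (parents[i] - 1);
    const int *h0 = hp + (size_t)L * base;
    const int *h1 = hp + (size_t)L * (base + 1);
    int *o = op + (size_t)L * i;
    int cur = bits.next();
    double pos = 0.0;
    double nextx = -std::log(unif_rand());
    o[0] = cur ? h1[0] : h0[0];
    for (int j = 1; j < L; ++j) {
      switch (type[j - 1]) {
      case 1:
        cur = bits.next();
        pos = 0.0;
        nextx = -std::log(unif_rand());
        break;
      case 2:
        pos += mapd[j - 1];
        while (pos >= nextx) {
          cur = 1 - cur;
          nextx += -std::log(unif_rand());
        }
        break;
      default:
        break;
      }
      o[j] = cur ? h1[j] : h0[j];
    }
  }
  return out;
}
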