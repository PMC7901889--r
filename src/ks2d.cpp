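#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Fasano-Franceschini two-sample 2-D KS statistic.  Quadrants are open:
// points lying on either dividing line through the origin point are
// excluded from all four quadrant counts of both samples.

static void quadrantFractions(double ox, double oy,
                              const double* x, const double* y,
                              const int* idx, int n, int ntot,
                              double f[4]) {
  int c[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    const double px = x[idx[i]], py = y[idx[i]];
    if (px > ox) {
      if (py > oy) ++c[0];
      else if (py < oy) ++c[3];
    } else if (px < ox) {
      if (py > oy) ++c[1];
      else if (py < oy) ++c[2];
    }
  }
  (void) ntot;
  for (int q = 0; q < 4; ++q) f[q] = (double) c[q] / (double) n;
}

static double ks2d_D(const double* x, const double* y,
                     const std::vector<int>& ia, const std::vector<int>& ib) {
  const int na = (int) ia.size(), nb = (int) ib.size();
  double d1 = 0.0, d2 = 0.0;
  double fa[4], fb[4];
  for (int i = 0; i < na; ++i) {
    const double ox = x[ia[i]], oy = y[ia[i]];
    quadrantFractions(ox, oy, x, y, ia.data(), na, na, fa);
    quadrantFractions(ox, oy, x, y, ib.data(), nb, nb, fb);
    for (int q = 0; q < 4; ++q) {
      const double d = std::fabs(fa[q] - fb[q]);
      if (d > d1) d1 = d;
    }
  }
  for (int i = 0; i < nb; ++i) {
    const double ox = x[ib[i]], oy = y[ib[i]];
    quadrantFractions(ox, oy, x, y, ia.data(), na, na, fa);
    quadrantFractions(ox, oy, x, y, ib.data(), nb, nb, fb);
    for (int q = 0; q < 4; ++q) {
      const double d = std::fabs(fa[q] - fb[q]);
      if (d > d2) d2 = d;
    }
  }
  return 0.5 * (d1 + d2);
}

// [[Rcpp::export(name = ".ks2dStatCpp")]]
double ks2d_stat_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  std::vector<double> x(na + nb), y(na + nb);
  std::vector<int> ia(na), ib(nb);
  for (int i = 0; i < na; ++i) {
    x[i] = a(i, 0); y[i] = a(i, 1); ia[i] = i;
  }
  for (int i = 0; i < nb; ++i) {
    x[na + i] = b(i, 0); y[na + i] = b(i, 1); ib[i] = na + i;
  }
  return ks2d_D(x.data(), y.data(), ia, ib);
}

// Permutation null: reshuffle the pooled labels B times and recompute D.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export(name = ".ks2dPermCpp")]]
NumericVector ks2d_perm_cpp(NumericMatrix pool, int n1, int B) {
  const int n = pool.nrow();
  if (n1 <= 0 || n1 >= n) stop("invalid split");
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pool(i, 0); y[i] = pool(i, 1); }
  std::vector<int> perm(n);
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int) std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    std::vector<int> ia(perm.begin(), perm.begin() + n1);
    std::vector<int> ib(perm.begin() + n1, perm.end());
    out[b] = ks2d_D(x.data(), y.data(), ia, ib);
  }
  return out;
}
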