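#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Windowed Pearson statistics via prefix sums: each window's sums are O(1)
// after one O(N) pass, so a K x M diagram costs O(N + K*M).

static inline void cum2(const double* v, int n, double* s, double* ss) {
  double a = 0.0, b = 0.0;
  s[0] = 0.0; ss[0] = 0.0;
  for (int i = 0; i < n; ++i) {
    a += v[i]; b += v[i] * v[i];
    s[i + 1] = a; ss[i + 1] = b;
  }
}

static inline void cumprod2(const double* x, const double* y, int n, double* s) {
  double a = 0.0;
  s[0] = 0.0;
  for (int i = 0; i < n; ++i) { a += x[i] * y[i]; s[i + 1] = a; }
}

// Relative tolerance separating a genuinely constant window (variance lost
// to cancellation, ~eps^1) from real variation.
static const double REL_VAR_TOL = 1e-14;

// [[Rcpp::export(name = ".xcorrDiagramCpp")]]
NumericMatrix xcorr_diagram_cpp(NumericVector x, NumericVector y,
                                IntegerMatrix starts, IntegerVector lens) {
  const int n = x.size(), K = starts.nrow(), M = starts.ncol();
  std::vector<double> sx(n + 1), sxx(n + 1), sy(n + 1), syy(n + 1), sxy(n + 1);
  cum2(REAL(x), n, sx.data(), sxx.data());
  cum2(REAL(y), n, sy.data(), syy.data());
  cumprod2(REAL(x), REAL(y), n, sxy.data());
  NumericMatrix r(K, M);
  for (int m = 0; m < M; ++m) {
    const double L = (double) lens[m];
    for (int k = 0; k < K; ++k) {
      const int s0 = starts(k, m), s1 = s0 + lens[m];
      const double Sx = sx[s1] - sx[s0], Sy = sy[s1] - sy[s0];
      const double Qx = sxx[s1] - sxx[s0], Qy = syy[s1] - syy[s0];
      const double vx = L * Qx - Sx * Sx;
      const double vy = L * Qy - Sy * Sy;
      if (vx <= REL_VAR_TOL * L * Qx || vy <= REL_VAR_TOL * L * Qy ||
          vx <= 0.0 || vy <= 0.0) {
        r(k, m) = NA_REAL;
        continue;
      }
      const double cv = L * (sxy[s1] - sxy[s0]) - Sx * Sy;
      double val = cv / std::sqrt(vx * vy);
      if (val > 1.0) val = 1.0;
      if (val < -1.0) val = -1.0;
      r(k, m) = val;
    }
  }
  return r;
}

// Observed diagram plus surrogate exceedance counts.  For each replicate j
// the pair (xs[,j], ys[,j]) is run over the same grid; a cell counts as
// exceeded when |r_surr| >= |r_obs|, compared through the cross-multiplied
// form cov_s^2 * vx_o * vy_o >= cov_o^2 * vx_s * vy_s (no sqrt, no division).
// [[Rcpp::export(name = ".pairExceedCpp")]]
List pair_exceed_cpp(NumericVector x, NumericVector y,
                     NumericMatrix xs, NumericMatrix ys,
                     IntegerMatrix starts, IntegerVector lens) {
  const int n = x.size(), K = starts.nrow(), M = starts.ncol();
  const int ns = xs.ncol();
  if (ys.ncol() != ns || xs.nrow() != n || ys.nrow() != n)
    stop("surrogate matrices must be N x nSurrogates");

  NumericMatrix r = xcorr_diagram_cpp(x, y, starts, lens);

  // per-cell observed cov^2 and vx*vy for the comparison
  std::vector<double> sx(n + 1), sxx(n + 1), sy(n + 1), syy(n + 1), sxy(n + 1);
  cum2(REAL(x), n, sx.data(), sxx.data());
  cum2(REAL(y), n, sy.data(), syy.data());
  cumprod2(REAL(x), REAL(y), n, sxy.data());
  const int nc = K * M;
  std::vector<double> cov2o(nc), deno(nc);
  std::vector<char> valid(nc);
  for (int m = 0; m < M; ++m) {
    const double L = (double) lens[m];
    for (int k = 0; k < K; ++k) {
      const int idx = m * K + k;
      const int s0 = starts(k, m), s1 = s0 + lens[m];
      if (ISNA(r(k, m)) || NumericMatrix::is_na(r(k, m))) {
        valid[idx] = 0; continue;
      }
      const double Sx = sx[s1] - sx[s0], Sy = sy[s1] - sy[s0];
      const double vx = L * (sxx[s1] - sxx[s0]) - Sx * Sx;
      const double vy = L * (syy[s1] - syy[s0]) - Sy * Sy;
      const double cv = L * (sxy[s1] - sxy[s0]) - Sx * Sy;
      cov2o[idx] = cv * cv;
      deno[idx] = vx * vy;
      valid[idx] = 1;
    }
  }

  IntegerMatrix g(K, M);
  int* gp = INTEGER(g);
  const int* startp = INTEGER(starts);
  const int* lenp = INTEGER(lens);
  std::vector<double> tx(n + 1), txx(n + 1), ty(n + 1), tyy(n + 1), txy(n + 1);
  const double* txp = tx.data();
  const double* txxp = txx.data();
  const double* typ = ty.data();
  const double* tyyp = tyy.data();
  const double* txyp = txy.data();
  for (int j = 0; j < ns; ++j) {
    const double* xj = &xs(0, j);
    const double* yj = &ys(0, j);
    cum2(xj, n, tx.data(), txx.data());
    cum2(yj, n, ty.data(), tyy.data());
    cumprod2(xj, yj, n, txy.data());
    for (int m = 0; m < M; ++m) {
      const double L = (double) lenp[m];
      const int Lm = lenp[m];
      const int* scol = startp + (size_t) m * K;
      const char* vcol = valid.data() + (size_t) m * K;
      const double* c2col = cov2o.data() + (size_t) m * K;
      const double* dncol = deno.data() + (size_t) m * K;
      int* gcol = gp + (size_t) m * K;
      for (int k = 0; k < K; ++k) {
        if (!vcol[k]) continue;
        const int s0 = scol[k], s1 = s0 + Lm;
        const double Sx = txp[s1] - txp[s0], Sy = typ[s1] - typ[s0];
        const double Qx = txxp[s1] - txxp[s0], Qy = tyyp[s1] - tyyp[s0];
        const double vx = L * Qx - Sx * Sx;
        const double vy = L * Qy - Sy * Sy;
        if (vx <= REL_VAR_TOL * L * Qx || vy <= REL_VAR_TOL * L * Qy ||
            vx <= 0.0 || vy <= 0.0)
          continue;                       // undefined surrogate cell
        const double cv = L * (txyp[s1] - txyp[s0]) - Sx * Sy;
        if (cv * cv * dncol[k] >= c2col[k] * vx * vy)
          gcol[k] += 1;
      }
    }
  }
  return List::create(Named("r") = r, Named("g") = g);
}
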