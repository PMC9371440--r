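#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Classic DTW dynamic program: absolute-difference local cost, unit
// steps (match / insert / delete), optional Sakoe-Chiba band (band < 0
// means unconstrained).
static double dtw_core(const double* x, int n, const double* y, int m,
                       int band) {
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    int jlo = 1, jhi = m;
    if (band >= 0) {
      jlo = std::max(1, i - band);
      jhi = std::min(m, i + band);
    }
    for (int j = jlo; j <= jhi; ++j) {
      double cost = std::fabs(x[i - 1] - y[j - 1]);
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = cost + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double dtw_dist_cpp(NumericVector x, NumericVector y, int band) {
  return dtw_core(x.begin(), x.size(), y.begin(), y.size(), band);
}

// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix series, int band) {
  int n = series.nrow(), m = series.ncol();
  // copy rows into contiguous buffers (R matrices are column-major)
  std::vector<std::vector<double> > rows(n, std::vector<double>(m));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) rows[i][j] = series(i, j);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(rows[i].data(), m, rows[j].data(), m, band);
      out(i, j) = d;
      out(j, i) = d;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
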