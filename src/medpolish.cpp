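#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median of finite values; NaN/NA entries ignored. Returns 0 when empty so
// an all-missing row/column sweeps nothing.
static double med(std::vector<double>& v) {
  if (v.empty()) return 0.0;
  size_t n = v.size(), h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Two-way median polish: alternate row/column median sweeps until the
// largest absolute sweep is below tol or max_iter is reached. Returns the
// residual matrix (NAs preserved).
// [[Rcpp::export]]
NumericMatrix cpp_medpolish(const NumericMatrix& x, double tol, int max_iter) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix r = clone(x);
  std::vector<double> buf;
  for (int it = 0; it < max_iter; ++it) {
    double sweep_max = 0.0;
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int j = 0; j < nc; ++j)
        if (R_finite(r(i, j))) buf.push_back(r(i, j));
      double m = med(buf);
      if (std::abs(m) > sweep_max) sweep_max = std::abs(m);
      for (int j = 0; j < nc; ++j) r(i, j) -= m;
    }
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int i = 0; i < nr; ++i)
        if (R_finite(r(i, j))) buf.push_back(r(i, j));
      double m = med(buf);
      if (std::abs(m) > sweep_max) sweep_max = std::abs(m);
      for (int i = 0; i < nr; ++i) r(i, j) -= m;
    }
    if (sweep_max < tol) break;
  }
  return r;
}
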