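#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1-D squared distance transform.
// f: squared distances so far; writes result into d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

//' Squared Euclidean distance transform
//'
//' For every pixel, squared distance (in pixels) to the nearest TRUE pixel
//' of `feature`. Pixels where `feature` is TRUE get 0. If `feature` has no
//' TRUE pixel, all distances are Inf.
//'
//' @param feature logical matrix of feature pixels.
//' @return numeric matrix of squared pixel distances.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix edt_sq(LogicalMatrix feature) {
  const int nr = feature.nrow(), nc = feature.ncol();
  // large finite sentinel: Inf would give Inf - Inf = NaN inside the
  // lower-envelope recursion and corrupt the transform
  const double BIG = 1e18;
  NumericMatrix out(nr, nc);
  // column pass
  std::vector<double> f(nr), d(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = feature(i, j) ? 0.0 : BIG;
    dt1d(f, d);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // row pass
  std::vector<double> fr(nc), dr(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) fr[j] = std::min(out(i, j), BIG);
    dt1d(fr, dr);
    for (int j = 0; j < nc; ++j)
      out(i, j) = (dr[j] >= BIG / 2) ?
        std::numeric_limits<double>::infinity() : dr[j];
  }
  return out;
}

//' Connected-component labeling
//'
//' Labels TRUE pixels of a binary mask with consecutive integers (1..k),
//' background 0. 4- or 8-connectivity.
//'
//' @param mask logical matrix.
//' @param connectivity 4 or 8.
//' @return integer matrix of labels.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* drs = connectivity == 4 ? dr4 : dr8;
  const int* dcs = connectivity == 4 ? dc4 : dc8;
  const int nd = connectivity;
  int cur = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++cur;
      stack.push_back(i + j * nr);
      lab(i, j) = cur;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < nd; ++d) {
          int qi = pi + drs[d], qj = pj + dcs[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = cur;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
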