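#include <Rcpp.h>
using namespace Rcpp;

// Median-of-3 filter along the columns (z axis) of an [n, nz] matrix with
// reflected edges: windows at the ends are [x1,x1,x2] and [x(nz-1),xnz,xnz].
// [[Rcpp::export(rng = false)]]
NumericMatrix median3_z(NumericMatrix m) {
  const int n = m.nrow(), nz = m.ncol();
  NumericMatrix out(n, nz);
  if (nz == 1) { out(_, 0) = m(_, 0); return out; }
  for (int k = 0; k < nz; ++k) {
    const double *a = &m(0, k > 0 ? k - 1 : 0);
    const double *b = &m(0, k);
    const double *c = &m(0, k < nz - 1 ? k + 1 : nz - 1);
    double *o = &out(0, k);
    for (int i = 0; i < n; ++i) {
      double lo = a[i] < b[i] ? a[i] : b[i];
      double hi = a[i] < b[i] ? b[i] : a[i];
      o[i] = c[i] < lo ? lo : (c[i] > hi ? hi : c[i]);
    }
  }
  return out;
}

// First local maximum above `floor` along each row of an [n, nz] matrix:
// strictly rising into the sample, not rising out of it; plateau ties
// resolve to the shallowest sample. Returns 1-based indices, 0 = none.
// [[Rcpp::export(rng = false)]]
IntegerVector first_local_max(NumericMatrix m, double floor_) {
  const int n = m.nrow(), nz = m.ncol();
  IntegerVector idx(n, 0);
  std::vector<bool> done(n, false);
  int remaining = n;
  for (int k = 0; k < nz && remaining > 0; ++k) {
    const double *b = &m(0, k);
    const double *a = k > 0 ? &m(0, k - 1) : nullptr;
    const double *c = k < nz - 1 ? &m(0, k + 1) : nullptr;
    for (int i = 0; i < n; ++i) {
      if (done[i]) continue;
      double v = b[i];
      if (v <= floor_) continue;
      if (a && v <= a[i]) continue;
      if (c && v < c[i]) continue;
      idx[i] = k + 1;
      done[i] = true;
      --remaining;
    }
  }
  return idx;
}

// In-place style running suffix maximum along columns of an [n, nz] matrix:
// out[, k] = max(m[, k], ..., m[, nz]).
// [[Rcpp::export(rng = false)]]
NumericMatrix suffix_max_z(NumericMatrix m) {
  const int n = m.nrow(), nz = m.ncol();
  NumericMatrix out = clone(m);
  for (int k = nz - 2; k >= 0; --k) {
    double *cur = &out(0, k);
    const double *nxt = &out(0, k + 1);
    for (int i = 0; i < n; ++i)
      if (nxt[i] > cur[i]) cur[i] = nxt[i];
  }
  return out;
}
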