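#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zero-phase (forward-reverse) IIR filtering of every column of a matrix.
//
// Direct-form-II-transposed recursion with the filter polynomials padded to
// a common length, processed in blocks of columns so the per-sample state
// update vectorizes across columns. Odd-reflection padding of 3 * order at
// both ends (scipy/MATLAB filtfilt convention).

static const int BLK = 16;

// one directional pass over a row-major block buffer of width w; the state
// is initialized to zi (steady-state step response) scaled by the first
// processed sample of each column, as in scipy/MATLAB filtfilt
static void pass_block(const std::vector<double>& b,
                       const std::vector<double>& a,
                       const std::vector<double>& zi,
                       double* buf, int m, int w, bool reverse) {
  const int nz = (int)b.size() - 1;
  std::vector<double> z((size_t)nz * w, 0.0);
  const double* first = buf + (size_t)(reverse ? m - 1 : 0) * w;
  for (int j = 0; j < nz; ++j) {
    for (int k = 0; k < w; ++k) z[(size_t)j * w + k] = zi[j] * first[k];
  }
  for (int s = 0; s < m; ++s) {
    double* row = buf + (size_t)(reverse ? m - 1 - s : s) * w;
    for (int k = 0; k < w; ++k) {
      const double xi = row[k];
      const double yi = b[0] * xi + z[k];
      for (int j = 0; j < nz - 1; ++j) {
        z[(size_t)j * w + k] = b[j + 1] * xi + z[(size_t)(j + 1) * w + k]
          - a[j + 1] * yi;
      }
      z[(size_t)(nz - 1) * w + k] = b[nz] * xi - a[nz] * yi;
      row[k] = yi;
    }
  }
}

// [[Rcpp::export(name = ".filtfilt_mat_zi")]]
NumericMatrix filtfilt_mat(NumericVector b, NumericVector a, NumericMatrix x,
                           NumericVector zi) {
  const int n = x.nrow(), nc = x.ncol();
  const int nz = std::max(b.size(), a.size()) - 1;
  if (a.size() == 0 || a[0] == 0.0) stop("a[1] must be nonzero");
  std::vector<double> bv(nz + 1, 0.0), av(nz + 1, 0.0);
  for (int j = 0; j < b.size(); ++j) bv[j] = b[j] / a[0];
  for (int j = 0; j < a.size(); ++j) av[j] = a[j] / a[0];
  if ((int)zi.size() != nz) stop("zi must have length max(len(a), len(b)) - 1");
  std::vector<double> ziv(zi.begin(), zi.end());
  int pad = 3 * nz;
  if (pad >= n) pad = n - 1;
  if (pad < 0) pad = 0;
  const int m = n + 2 * pad;
  NumericMatrix out(n, nc);
  std::vector<double> buf((size_t)m * BLK);
  for (int c0 = 0; c0 < nc; c0 += BLK) {
    const int w = std::min(BLK, nc - c0);
    // interleave block columns row-major with odd-reflection padding
    for (int k = 0; k < w; ++k) {
      const double* col = &x(0, c0 + k);
      for (int i = 0; i < pad; ++i) {
        buf[(size_t)i * w + k] = 2.0 * col[0] - col[pad - i];
      }
      for (int i = 0; i < n; ++i) buf[(size_t)(pad + i) * w + k] = col[i];
      for (int i = 0; i < pad; ++i) {
        buf[(size_t)(pad + n + i) * w + k] = 2.0 * col[n - 1] - col[n - 2 - i];
      }
    }
    pass_block(bv, av, ziv, buf.data(), m, w, false);
    pass_block(bv, av, ziv, buf.data(), m, w, true);
    for (int k = 0; k < w; ++k) {
      double* col = &out(0, c0 + k);
      for (int i = 0; i < n; ++i) col[i] = buf[(size_t)(pad + i) * w + k];
    }
  }
  return out;
}
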