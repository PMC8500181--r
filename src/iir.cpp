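// Zero-phase IIR filtering kernel: direct-form-II-transposed passes run
// forward and backward over each column, with odd-reflection padding
// handled by the R caller's pad length.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static void iirPass(const std::vector<double>& b, const std::vector<double>& a,
                    const std::vector<double>& zi, std::vector<double>& x) {
  const size_t nz = b.size() - 1;  // b and a are padded to equal length
  // steady-state initial conditions scaled by the first sample remove the
  // step-response transient (the lfilter_zi construction)
  std::vector<double> z(nz, 0.0);
  for (size_t k = 0; k < nz && k < zi.size(); ++k) z[k] = zi[k] * x[0];
  for (size_t i = 0; i < x.size(); ++i) {
    const double xi = x[i];
    const double yi = b[0] * xi + z[0];
    for (size_t k = 1; k < nz; ++k)
      z[k - 1] = b[k] * xi + z[k] - a[k] * yi;
    z[nz - 1] = b[nz] * xi - a[nz] * yi;
    x[i] = yi;
  }
}

// [[Rcpp::export(name = ".iirFiltfiltMat")]]
NumericMatrix iirFiltfiltMat(NumericVector b, NumericVector a,
                             NumericVector zi, NumericMatrix x, int pad) {
  const size_t len = std::max(b.size(), a.size());
  std::vector<double> bb(len, 0.0), aa(len, 0.0);
  std::copy(b.begin(), b.end(), bb.begin());
  std::copy(a.begin(), a.end(), aa.begin());
  std::vector<double> zz(zi.begin(), zi.end());
  const int n = x.nrow(), nc = x.ncol();
  if (pad > n - 1) pad = n - 1;
  if (pad < 0) pad = 0;
  NumericMatrix out(n, nc);
  std::vector<double> buf(n + 2 * pad);
  for (int j = 0; j < nc; ++j) {
    // odd reflection about both end samples
    for (int i = 0; i < pad; ++i)
      buf[i] = 2.0 * x(0, j) - x(pad - i, j);
    for (int i = 0; i < n; ++i) buf[pad + i] = x(i, j);
    for (int i = 0; i < pad; ++i)
      buf[pad + n + i] = 2.0 * x(n - 1, j) - x(n - 2 - i, j);
    iirPass(bb, aa, zz, buf);
    std::reverse(buf.begin(), buf.end());
    iirPass(bb, aa, zz, buf);
    std::reverse(buf.begin(), buf.end());
    for (int i = 0; i < n; ++i) out(i, j) = buf[pad + i];
  }
  return out;
}
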