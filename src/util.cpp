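// Small grid utilities: 26-connected component labelling and a separable
// box filter, both used by the focal-region analysis.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

typedef long long ll;

// [[Rcpp::export(name = ".label_components26")]]
IntegerVector label_components26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const ll N = (ll)nx * ny * nz;
  IntegerVector lab(N, 0);
  std::vector<ll> stack;
  int cur = 0;
  for (ll s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      ll q = stack.back(); stack.pop_back();
      int i = (int)(q % nx), j = (int)((q / nx) % ny), k = (int)(q / ((ll)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            ll qq = ii + (ll)nx * (jj + (ll)ny * kk);
            if (mask[qq] && !lab[qq]) { lab[qq] = cur; stack.push_back(qq); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Separable moving-average filter of odd width, replicate padding.
// [[Rcpp::export(name = ".boxfilter3d")]]
NumericVector boxfilter3d(NumericVector x, IntegerVector dims, int width) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const ll N = (ll)nx * ny * nz;
  const int h = width / 2;
  std::vector<double> a(x.begin(), x.end()), b(N);
  auto pass = [&](int n, ll stride, ll nlines, auto line_base) {
    for (ll L = 0; L < nlines; ++L) {
      ll base = line_base(L);
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int d = -h; d <= h; ++d) {
          int ii = i + d;
          if (ii < 0) ii = 0;
          if (ii >= n) ii = n - 1;
          s += a[base + (ll)ii * stride];
        }
        b[base + (ll)i * stride] = s / width;
      }
    }
    std::swap(a, b);
  };
  // x lines
  pass(nx, 1, (ll)ny * nz, [&](ll L) { return L * nx; });
  // y lines
  pass(ny, nx, (ll)nx * nz, [&](ll L) {
    ll k = L / nx, i = L % nx;
    return i + (ll)nx * ny * k;
  });
  // z lines
  pass(nz, (ll)nx * ny, (ll)nx * ny, [&](ll L) { return L; });
  NumericVector out(N);
  for (ll q = 0; q < N; ++q) out[q] = a[q];
  out.attr("dim") = dims;
  return out;
}
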