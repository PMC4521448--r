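// Explicit finite-difference stepper for the Pennes bioheat equation
//   rho C dT/dt = div(k grad T) + rho Q + rho S - rho_b c_b rho omega (T - Tb)
// on a rectilinear grid.  Face conductivities are harmonic means; boundary
// voxels come in two kinds:
//   btype 1: fixed temperature (Dirichlet), never updated, conducts normally
//   btype 2: ambient medium, never updated; the interface flux into an
//            adjacent tissue voxel is F - h (T_tissue - T_ambient) per unit
//            face area (convective/Neumann mixed condition; h = 0 gives a
//            pure imposed-flux condition).
// Optional vascular-shutdown multiplier on the perfusion term: 1 below T50,
// linear to 0 between T50 and T51, 0 above.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

typedef long long ll;

// [[Rcpp::export(name = ".bioheat_run")]]
List bioheat_run(IntegerVector dims,
                 NumericVector xs, NumericVector ys, NumericVector zs,
                 NumericVector rhoC, NumericVector kcond,
                 NumericVector volSrc,   // rho*Q + rho*S, W m^-3
                 NumericVector perfC,    // rho_b c_b rho omega, W m^-3 K^-1
                 double Tb,
                 IntegerVector btype, NumericVector bh, NumericVector bF,
                 int shutdown, double T50, double T51,
                 NumericVector T0, double dt, int nsteps,
                 IntegerVector probe_idx, int record_every) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const ll N = (ll)nx * ny * nz;
  const ll sx = 1, sy = nx, sz = (ll)nx * ny;
  if ((ll)T0.size() != N) stop("T0 size mismatch");

  std::vector<double> idxf(nx > 1 ? nx - 1 : 1, 0.0),
      idyf(ny > 1 ? ny - 1 : 1, 0.0), idzf(nz > 1 ? nz - 1 : 1, 0.0);
  std::vector<double> idxc(nx), idyc(ny), idzc(nz);
  for (int i = 0; i + 1 < nx; ++i) idxf[i] = 1.0 / (xs[i + 1] - xs[i]);
  for (int j = 0; j + 1 < ny; ++j) idyf[j] = 1.0 / (ys[j + 1] - ys[j]);
  for (int k = 0; k + 1 < nz; ++k) idzf[k] = 1.0 / (zs[k + 1] - zs[k]);
  auto centr = [](const NumericVector& v, int n, std::vector<double>& out) {
    for (int i = 0; i < n; ++i) {
      double lo = (i > 0) ? v[i] - v[i - 1] : (n > 1 ? v[1] - v[0] : 1.0);
      double hi = (i + 1 < n) ? v[i + 1] - v[i] : (n > 1 ? v[n - 1] - v[n - 2] : 1.0);
      out[i] = 2.0 / (lo + hi);
    }
  };
  centr(xs, nx, idxc); centr(ys, ny, idyc); centr(zs, nz, idzc);

  std::vector<double> T(T0.begin(), T0.end()), Tn(N, 0.0);

  const int nprobe = probe_idx.size();
  int nrecsteps = (record_every > 0) ? (nsteps + record_every - 1) / record_every : 0;
  NumericMatrix probes(nrecsteps, nprobe);
  NumericVector maxTrec(nrecsteps), trec(nrecsteps);
  int ri = 0;

  auto faceflux = [&](ll q, ll qn, double invd) -> double {
    // flux density into voxel q across the face shared with qn, per unit area
    int bt = btype[qn];
    if (bt == 2) {
      return bF[qn] - bh[qn] * (T[q] - T[qn]);
    }
    double ka = kcond[q], kb = kcond[qn];
    double kf = (ka > 0.0 && kb > 0.0) ? 2.0 * ka * kb / (ka + kb) : 0.0;
    return kf * (T[qn] - T[q]) * invd;
  };

  for (int n = 0; n < nsteps; ++n) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        ll base = (ll)j * sy + (ll)k * sz;
        for (int i = 0; i < nx; ++i) {
          ll q = base + i;
          if (btype[q] != 0) { Tn[q] = T[q]; continue; }
          double acc = 0.0;
          if (i + 1 < nx) acc += faceflux(q, q + sx, idxf[i]) * idxc[i];
          if (i > 0)      acc += faceflux(q, q - sx, idxf[i - 1]) * idxc[i];
          if (j + 1 < ny) acc += faceflux(q, q + sy, idyf[j]) * idyc[j];
          if (j > 0)      acc += faceflux(q, q - sy, idyf[j - 1]) * idyc[j];
          if (k + 1 < nz) acc += faceflux(q, q + sz, idzf[k]) * idzc[k];
          if (k > 0)      acc += faceflux(q, q - sz, idzf[k - 1]) * idzc[k];
          double pc = perfC[q];
          if (pc != 0.0 && shutdown) {
            double Tq = T[q];
            double m = (Tq <= T50) ? 1.0 : (Tq >= T51 ? 0.0 : (T51 - Tq) / (T51 - T50));
            pc *= m;
          }
          double rhs = acc + volSrc[q] - pc * (T[q] - Tb);
          Tn[q] = T[q] + dt * rhs / rhoC[q];
        }
      }
    std::swap(T, Tn);

    if (record_every > 0 && (n % record_every == record_every - 1 || n == nsteps - 1)) {
      if (ri < nrecsteps) {
        double mx = -1e300;
        for (ll q = 0; q < N; ++q) if (T[q] > mx) mx = T[q];
        if (!R_finite(mx) || mx > 150.0 || mx < -50.0)
          stop("bioheat solver out of physical bounds (max T = %g) at step %d", mx, n + 1);
        for (int p = 0; p < nprobe; ++p) probes(ri, p) = T[probe_idx[p]];
        maxTrec[ri] = mx;
        trec[ri] = (n + 1) * dt;
        ++ri;
      }
    }
    if ((n & 63) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector Tfin(N);
  for (ll q = 0; q < N; ++q) Tfin[q] = T[q];
  return List::create(_["T"] = Tfin, _["probes"] = probes,
                      _["maxT"] = maxTrec, _["t"] = trec, _["nrec"] = ri);
}
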