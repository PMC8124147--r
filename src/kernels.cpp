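#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Clamped point-source kernel: 1/(4*pi*kappa*max(r, clamp)).
// All lengths in metres, strengths in watts, kappa in W/(K m).

// Direct superposition of point heat sources over an arbitrary set of
// evaluation points. O(N_points * N_sources); this is the oracle path.
// [[Rcpp::export(name = ".cpp_direct_sum")]]
NumericVector cpp_direct_sum(NumericMatrix pts, NumericMatrix src,
                             NumericVector strength, double clamp,
                             double kappa) {
  const R_xlen_t np = pts.nrow(), ns = src.nrow();
  const double c0 = 1.0 / (4.0 * M_PI * kappa);
  NumericVector out(np);
  std::vector<double> sx(ns), sy(ns), sz(ns), sw(ns);
  for (R_xlen_t j = 0; j < ns; ++j) {
    sx[j] = src(j, 0); sy[j] = src(j, 1); sz[j] = src(j, 2);
    sw[j] = strength[j];
  }
  std::vector<double> px(np), py(np), pz(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
  }
  // source-outer loop: the accumulator stays cache-resident
  for (R_xlen_t j = 0; j < ns; ++j) {
    const double qx = sx[j], qy = sy[j], qz = sz[j], w = sw[j];
    for (R_xlen_t i = 0; i < np; ++i) {
      const double dx = px[i] - qx, dy = py[i] - qy, dz = pz[i] - qz;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < clamp) r = clamp;
      out[i] += w / r;
    }
  }
  for (R_xlen_t i = 0; i < np; ++i) out[i] *= c0;
  return out;
}

// Direct superposition evaluated on a regular grid (axes given), avoiding
// materialising the point matrix in R. Returns values in x-fastest order.
// [[Rcpp::export(name = ".cpp_direct_sum_grid")]]
NumericVector cpp_direct_sum_grid(NumericVector gx, NumericVector gy,
                                  NumericVector gz, NumericMatrix src,
                                  NumericVector strength, double clamp,
                                  double kappa) {
  const R_xlen_t nx = gx.size(), ny = gy.size(), nz = gz.size();
  const R_xlen_t ns = src.nrow();
  const double c0 = 1.0 / (4.0 * M_PI * kappa);
  NumericVector out(nx * ny * nz);
  std::vector<double> sx(ns), sy(ns), sz(ns), sw(ns);
  for (R_xlen_t j = 0; j < ns; ++j) {
    sx[j] = src(j, 0); sy[j] = src(j, 1); sz[j] = src(j, 2);
    sw[j] = strength[j];
  }
  // source-outer loops keep the field accumulator cache-resident and let
  // the x-inner loop reuse the per-plane squared distance
  const double clamp2 = clamp * clamp;
  std::vector<double> ax(nx);
  double *o = REAL(out);
  for (R_xlen_t j = 0; j < ns; ++j) {
    const double qx = sx[j], qy = sy[j], qz = sz[j], w = sw[j];
    for (R_xlen_t kx = 0; kx < nx; ++kx) {
      const double dx = gx[kx] - qx;
      ax[kx] = dx * dx;
    }
    for (R_xlen_t kz = 0; kz < nz; ++kz) {
      const double dz = gz[kz] - qz, dz2 = dz * dz;
      for (R_xlen_t ky = 0; ky < ny; ++ky) {
        const double dy = gy[ky] - qy, dyz2 = dy * dy + dz2;
        double *row = o + (kz * ny + ky) * nx;
        for (R_xlen_t kx = 0; kx < nx; ++kx) {
          double r2 = ax[kx] + dyz2;
          if (r2 < clamp2) r2 = clamp2;
          row[kx] += w / std::sqrt(r2);
        }
      }
    }
  }
  const R_xlen_t ntot = nx * ny * nz;
  for (R_xlen_t i = 0; i < ntot; ++i) o[i] *= c0;
  return out;
}

// Near-field correction for the particle-mesh fast path. For each source the
// mesh sees eight cloud-in-cell image charges on the surrounding grid nodes;
// within a window of `ncorr` cells around the source this replaces their
// mesh-kernel contribution with the exact clamped kernel from the true
// source position. `field` is modified in place (x-fastest layout).
// [[Rcpp::export(name = ".cpp_cic_correct")]]
void cpp_cic_correct(NumericVector field, NumericVector gx, NumericVector gy,
                     NumericVector gz, NumericMatrix src,
                     NumericVector strength, double clamp, double kappa,
                     int ncorr) {
  const int nx = gx.size(), ny = gy.size(), nz = gz.size();
  const R_xlen_t ns = src.nrow();
  const double c0 = 1.0 / (4.0 * M_PI * kappa);
  const double dx = nx > 1 ? gx[1] - gx[0] : 1.0;
  const double dy = ny > 1 ? gy[1] - gy[0] : 1.0;
  const double dz = nz > 1 ? gz[1] - gz[0] : 1.0;
  for (R_xlen_t s = 0; s < ns; ++s) {
    const double pxs = src(s, 0), pys = src(s, 1), pzs = src(s, 2);
    const double w = strength[s];
    // CIC deposition cell and weights
    double fx = (pxs - gx[0]) / dx, fy = (pys - gy[0]) / dy,
           fz = (pzs - gz[0]) / dz;
    int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
        iz = (int)std::floor(fz);
    if (ix < 0) ix = 0; if (ix > nx - 2) ix = nx > 1 ? nx - 2 : 0;
    if (iy < 0) iy = 0; if (iy > ny - 2) iy = ny > 1 ? ny - 2 : 0;
    if (iz < 0) iz = 0; if (iz > nz - 2) iz = nz > 1 ? nz - 2 : 0;
    const double tx = nx > 1 ? fx - ix : 0.0, ty = ny > 1 ? fy - iy : 0.0,
                 tz = nz > 1 ? fz - iz : 0.0;
    double wts[8];
    int dep[8][3];
    int ndep = 0;
    for (int c = 0; c < 8; ++c) {
      const int ax = c & 1, ay = (c >> 1) & 1, az = (c >> 2) & 1;
      if ((ax && nx == 1) || (ay && ny == 1) || (az && nz == 1)) continue;
      const double wc = (ax ? tx : 1.0 - tx) * (ay ? ty : 1.0 - ty) *
                        (az ? tz : 1.0 - tz);
      if (wc == 0.0) continue;
      dep[ndep][0] = ix + ax; dep[ndep][1] = iy + ay; dep[ndep][2] = iz + az;
      wts[ndep] = wc;
      ++ndep;
    }
    const int x0 = std::max(0, ix - ncorr), x1 = std::min(nx - 1, ix + 1 + ncorr);
    const int y0 = std::max(0, iy - ncorr), y1 = std::min(ny - 1, iy + 1 + ncorr);
    const int z0 = std::max(0, iz - ncorr), z1 = std::min(nz - 1, iz + 1 + ncorr);
    for (int kz = z0; kz <= z1; ++kz) {
      for (int ky = y0; ky <= y1; ++ky) {
        for (int kx = x0; kx <= x1; ++kx) {
          // exact contribution
          const double ex = gx[kx] - pxs, ey = gy[ky] - pys, ez = gz[kz] - pzs;
          double r = std::sqrt(ex * ex + ey * ey + ez * ez);
          if (r < clamp) r = clamp;
          double corr = w / r;
          // minus what the mesh already put there for this source
          for (int c = 0; c < ndep; ++c) {
            const double mx = (kx - dep[c][0]) * dx,
                         my = (ky - dep[c][1]) * dy,
                         mz = (kz - dep[c][2]) * dz;
            double rm = std::sqrt(mx * mx + my * my + mz * mz);
            if (rm < clamp) rm = clamp;
            corr -= w * wts[c] / rm;
          }
          field[(R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx + kx] += c0 * corr;
        }
      }
    }
  }
}
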