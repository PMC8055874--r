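#include <Rcpp.h>
using namespace Rcpp;

// Conservative flux-form divergence of D grad(phi) on a regular 3-D grid.
// Face diffusivities Dx, Dy, Dz are stored at the lower voxel of each face
// (the face between voxel i and i+1 along the axis); faces beyond the grid
// carry zero diffusivity, which together with zero D outside the brain
// enforces the no-flux boundary.
// [[Rcpp::export]]
NumericVector cpp_div_d_grad(NumericVector phi, NumericVector Dx,
                             NumericVector Dy, NumericVector Dz,
                             IntegerVector dims, NumericVector inv_h2) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double ihx = inv_h2[0], ihy = inv_h2[1], ihz = inv_h2[2];
  const int sx = 1, sy = nx, sz = nx * ny;
  NumericVector out(phi.size());
  const double *p = phi.begin(), *dx = Dx.begin(), *dy = Dy.begin(),
               *dz = Dz.begin();
  double *o = out.begin();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      int base = j * sy + k * sz;
      for (int i = 0; i < nx; ++i) {
        int id = base + i;
        double acc = 0.0;
        double pc = p[id];
        if (i + 1 < nx) acc += dx[id] * (p[id + sx] - pc) * ihx;
        if (i > 0)      acc -= dx[id - sx] * (pc - p[id - sx]) * ihx;
        if (j + 1 < ny) acc += dy[id] * (p[id + sy] - pc) * ihy;
        if (j > 0)      acc -= dy[id - sy] * (pc - p[id - sy]) * ihy;
        if (k + 1 < nz) acc += dz[id] * (p[id + sz] - pc) * ihz;
        if (k > 0)      acc -= dz[id - sz] * (pc - p[id - sz]) * ihz;
        o[id] = acc;
      }
    }
  }
  return out;
}

// Shift an array along one axis (1-based axis), zero fill: out[i] = a[i+by].
// [[Rcpp::export]]
NumericVector cpp_shift3(NumericVector a, IntegerVector dims, int axis,
                         int by) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(a.size());
  const int stride = (axis == 1) ? 1 : (axis == 2 ? nx : nx * ny);
  const int n_axis = (axis == 1) ? nx : (axis == 2 ? ny : nz);
  if (std::abs(by) >= n_axis) return out;
  const double *src = a.begin();
  double *dst = out.begin();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      int base = j * nx + k * nx * ny;
      for (int i = 0; i < nx; ++i) {
        int idx_axis = (axis == 1) ? i : (axis == 2 ? j : k);
        int from = idx_axis + by;
        if (from >= 0 && from < n_axis)
          dst[base + i] = src[base + i + by * stride];
      }
    }
  }
  return out;
}

// Harmonic face diffusivity along one axis: zero when either side is zero.
// [[Rcpp::export]]
NumericVector cpp_face_harmonic_zero(NumericVector D, IntegerVector dims,
                                     int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int stride = (axis == 1) ? 1 : (axis == 2 ? nx : nx * ny);
  const int n_axis = (axis == 1) ? nx : (axis == 2 ? ny : nz);
  NumericVector out(D.size());
  const double *d = D.begin();
  double *o = out.begin();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      int base = j * nx + k * nx * ny;
      for (int i = 0; i < nx; ++i) {
        int idx_axis = (axis == 1) ? i : (axis == 2 ? j : k);
        if (idx_axis + 1 >= n_axis) continue;
        int id = base + i;
        double a = d[id], b = d[id + stride];
        if (a > 0.0 && b > 0.0) o[id] = 2.0 * a * b / (a + b);
      }
    }
  }
  return out;
}

// Von Mises stress of a displacement field under isotropic linear
// elasticity: strains by central differences (zero displacement beyond the
// grid), sigma = 2 G eps + lambda tr(eps) I, vm = sqrt(3/2 s:s) of the
// deviatoric part.
// [[Rcpp::export]]
NumericVector cpp_von_mises(NumericVector u1, NumericVector u2,
                            NumericVector u3, NumericVector G,
                            IntegerVector dims, NumericVector h, double nu) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sx = 1, sy = nx, sz = nx * ny;
  const double ihx = 0.5 / h[0], ihy = 0.5 / h[1], ihz = 0.5 / h[2];
  NumericVector out(u1.size());
  const double *U[3] = {u1.begin(), u2.begin(), u3.begin()};
  const double *g = G.begin();
  double *o = out.begin();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      int base = j * sy + k * sz;
      for (int i = 0; i < nx; ++i) {
        int id = base + i;
        double du[3][3]; // du[a][b] = d u_b / d x_a
        for (int b = 0; b < 3; ++b) {
          const double *ub = U[b];
          double xp = (i + 1 < nx) ? ub[id + sx] : 0.0;
          double xm = (i > 0) ? ub[id - sx] : 0.0;
          double yp = (j + 1 < ny) ? ub[id + sy] : 0.0;
          double ym = (j > 0) ? ub[id - sy] : 0.0;
          double zp = (k + 1 < nz) ? ub[id + sz] : 0.0;
          double zm = (k > 0) ? ub[id - sz] : 0.0;
          du[0][b] = (xp - xm) * ihx;
          du[1][b] = (yp - ym) * ihy;
          du[2][b] = (zp - zm) * ihz;
        }
        double e11 = du[0][0], e22 = du[1][1], e33 = du[2][2];
        double e12 = 0.5 * (du[0][1] + du[1][0]);
        double e13 = 0.5 * (du[0][2] + du[2][0]);
        double e23 = 0.5 * (du[1][2] + du[2][1]);
        double gg = g[id];
        double lam = 2.0 * gg * nu / (1.0 - 2.0 * nu);
        double tr = e11 + e22 + e33;
        double s11 = 2.0 * gg * e11 + lam * tr;
        double s22 = 2.0 * gg * e22 + lam * tr;
        double s33 = 2.0 * gg * e33 + lam * tr;
        double s12 = 2.0 * gg * e12, s13 = 2.0 * gg * e13,
               s23 = 2.0 * gg * e23;
        double q = 0.5 * ((s11 - s22) * (s11 - s22) +
                          (s22 - s33) * (s22 - s33) +
                          (s33 - s11) * (s33 - s11)) +
                   3.0 * (s12 * s12 + s13 * s13 + s23 * s23);
        o[id] = q > 0.0 ? std::sqrt(q) : 0.0;
      }
    }
  }
  return out;
}
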