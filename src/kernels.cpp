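#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid convention shared with the R side: voxel centres at
// origin + index * voxel (0-based index), x fastest in memory.

static inline int idx3(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + (long long)ny * iz);
}

// Trilinear interpolation of map values at Cartesian positions.
// Positions outside the grid return 0 and are flagged.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector values, IntegerVector dims,
                   NumericVector origin, NumericVector voxel,
                   NumericMatrix coords) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  NumericVector out(n);
  LogicalVector oob(n);
  for (int p = 0; p < n; ++p) {
    double gx = (coords(p, 0) - origin[0]) / voxel[0];
    double gy = (coords(p, 1) - origin[1]) / voxel[1];
    double gz = (coords(p, 2) - origin[2]) / voxel[2];
    if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1) {
      out[p] = 0.0; oob[p] = true; continue;
    }
    int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
    if (ix >= nx - 1) ix = nx - 2;
    if (iy >= ny - 1) iy = ny - 2;
    if (iz >= nz - 1) iz = nz - 2;
    double fx = gx - ix, fy = gy - iy, fz = gz - iz;
    double v = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
          v += w * values[idx3(ix + dx, iy + dy, iz + dz, nx, ny)];
        }
    out[p] = v; oob[p] = false;
  }
  return List::create(_["value"] = out, _["oob"] = oob);
}

// Trilinear interpolation with the spatial gradient of the interpolant.
// [[Rcpp::export]]
List cpp_trilinear_grad(NumericVector values, IntegerVector dims,
                        NumericVector origin, NumericVector voxel,
                        NumericMatrix coords) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = coords.nrow();
  NumericVector out(n);
  NumericMatrix grad(n, 3);
  LogicalVector oob(n);
  for (int p = 0; p < n; ++p) {
    double gx = (coords(p, 0) - origin[0]) / voxel[0];
    double gy = (coords(p, 1) - origin[1]) / voxel[1];
    double gz = (coords(p, 2) - origin[2]) / voxel[2];
    if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1) {
      out[p] = 0.0; oob[p] = true; continue;
    }
    int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
    if (ix >= nx - 1) ix = nx - 2;
    if (iy >= ny - 1) iy = ny - 2;
    if (iz >= nz - 1) iz = nz - 2;
    double fx = gx - ix, fy = gy - iy, fz = gz - iz;
    double v = 0.0, dvx = 0.0, dvy = 0.0, dvz = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          double val = values[idx3(ix + dx, iy + dy, iz + dz, nx, ny)];
          double wx = dx ? fx : 1 - fx, wy = dy ? fy : 1 - fy, wz = dz ? fz : 1 - fz;
          double sx = dx ? 1.0 : -1.0, sy = dy ? 1.0 : -1.0, sz = dz ? 1.0 : -1.0;
          v += wx * wy * wz * val;
          dvx += sx * wy * wz * val;
          dvy += wx * sy * wz * val;
          dvz += wx * wy * sz * val;
        }
    out[p] = v;
    grad(p, 0) = dvx / voxel[0];
    grad(p, 1) = dvy / voxel[1];
    grad(p, 2) = dvz / voxel[2];
    oob[p] = false;
  }
  return List::create(_["value"] = out, _["grad"] = grad, _["oob"] = oob);
}

// Rasterize a sum of per-atom Gaussian mixtures onto the grid.
// amp, wexp: n_atoms x n_terms; each atom contributes
//   sum_g amp(a,g) * exp(-wexp(a,g) * r^2)
// within radius rcut[a] of its centre.
// [[Rcpp::export]]
NumericVector cpp_atom_density(IntegerVector dims, NumericVector origin,
                               NumericVector voxel, NumericMatrix coords,
                               NumericMatrix amp, NumericMatrix wexp,
                               NumericVector rcut) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = coords.nrow(), ng = amp.ncol();
  NumericVector out((long long)nx * ny * nz);
  for (int a = 0; a < na; ++a) {
    double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    double rc = rcut[a], rc2 = rc * rc;
    int ix0 = std::max(0, (int)std::ceil((cx - rc - origin[0]) / voxel[0]));
    int ix1 = std::min(nx - 1, (int)std::floor((cx + rc - origin[0]) / voxel[0]));
    int iy0 = std::max(0, (int)std::ceil((cy - rc - origin[1]) / voxel[1]));
    int iy1 = std::min(ny - 1, (int)std::floor((cy + rc - origin[1]) / voxel[1]));
    int iz0 = std::max(0, (int)std::ceil((cz - rc - origin[2]) / voxel[2]));
    int iz1 = std::min(nz - 1, (int)std::floor((cz + rc - origin[2]) / voxel[2]));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = origin[2] + iz * voxel[2] - cz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = origin[1] + iy * voxel[1] - cy;
        double dyz2 = dy * dy + dz * dz;
        if (dyz2 > rc2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = origin[0] + ix * voxel[0] - cx;
          double r2 = dx * dx + dyz2;
          if (r2 > rc2) continue;
          double v = 0.0;
          for (int g = 0; g < ng; ++g) v += amp(a, g) * std::exp(-wexp(a, g) * r2);
          out[idx3(ix, iy, iz, nx, ny)] += v;
        }
      }
    }
  }
  return out;
}

// Chain rule of a scalar functional E through the Gaussian rasterizer:
// given dE/drho on the grid, return dE/dx for each atom centre.
// [[Rcpp::export]]
NumericMatrix cpp_atom_density_grad(NumericVector dEdrho, IntegerVector dims,
                                    NumericVector origin, NumericVector voxel,
                                    NumericMatrix coords, NumericMatrix amp,
                                    NumericMatrix wexp, NumericVector rcut) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = coords.nrow(), ng = amp.ncol();
  NumericMatrix grad(na, 3);
  for (int a = 0; a < na; ++a) {
    double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    double rc = rcut[a], rc2 = rc * rc;
    int ix0 = std::max(0, (int)std::ceil((cx - rc - origin[0]) / voxel[0]));
    int ix1 = std::min(nx - 1, (int)std::floor((cx + rc - origin[0]) / voxel[0]));
    int iy0 = std::max(0, (int)std::ceil((cy - rc - origin[1]) / voxel[1]));
    int iy1 = std::min(ny - 1, (int)std::floor((cy + rc - origin[1]) / voxel[1]));
    int iz0 = std::max(0, (int)std::ceil((cz - rc - origin[2]) / voxel[2]));
    int iz1 = std::min(nz - 1, (int)std::floor((cz + rc - origin[2]) / voxel[2]));
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = origin[2] + iz * voxel[2] - cz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = origin[1] + iy * voxel[1] - cy;
        double dyz2 = dy * dy + dz * dz;
        if (dyz2 > rc2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = origin[0] + ix * voxel[0] - cx;
          double r2 = dx * dx + dyz2;
          if (r2 > rc2) continue;
          double s = 0.0;
          for (int g = 0; g < ng; ++g)
            s += 2.0 * wexp(a, g) * amp(a, g) * std::exp(-wexp(a, g) * r2);
          // d rho / d centre = +2 w (r - c)... rho depends on (x_vox - c):
          // d/dc exp(-w |v-c|^2) = 2 w (v - c) exp(.)
          double e = dEdrho[idx3(ix, iy, iz, nx, ny)] * s;
          gx += e * dx; gy += e * dy; gz += e * dz;
        }
      }
    }
    grad(a, 0) = gx; grad(a, 1) = gy; grad(a, 2) = gz;
  }
  return grad;
}

// Minimum distance from each voxel centre to any atom, capped at rmax.
// Used for model-based masking with a soft edge.
// [[Rcpp::export]]
NumericVector cpp_min_dist(IntegerVector dims, NumericVector origin,
                           NumericVector voxel, NumericMatrix coords,
                           double rmax) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = coords.nrow();
  NumericVector out((long long)nx * ny * nz, rmax);
  double rc2 = rmax * rmax;
  for (int a = 0; a < na; ++a) {
    double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    int ix0 = std::max(0, (int)std::ceil((cx - rmax - origin[0]) / voxel[0]));
    int ix1 = std::min(nx - 1, (int)std::floor((cx + rmax - origin[0]) / voxel[0]));
    int iy0 = std::max(0, (int)std::ceil((cy - rmax - origin[1]) / voxel[1]));
    int iy1 = std::min(ny - 1, (int)std::floor((cy + rmax - origin[1]) / voxel[1]));
    int iz0 = std::max(0, (int)std::ceil((cz - rmax - origin[2]) / voxel[2]));
    int iz1 = std::min(nz - 1, (int)std::floor((cz + rmax - origin[2]) / voxel[2]));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = origin[2] + iz * voxel[2] - cz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = origin[1] + iy * voxel[1] - cy;
        double dyz2 = dy * dy + dz * dz;
        if (dyz2 > rc2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = origin[0] + ix * voxel[0] - cx;
          double r2 = dx * dx + dyz2;
          long long k = idx3(ix, iy, iz, nx, ny);
          double d = std::sqrt(r2);
          if (d < out[k]) out[k] = d;
        }
      }
    }
  }
  return out;
}

// Soft quartic repulsion between point sets a (movable) and b (fixed),
// active below dmin: E = sum k * (dmin - d)^4, with gradient on set a.
// Pairs listed explicitly by 0-based index.
// [[Rcpp::export]]
List cpp_repulsion(NumericMatrix xa, NumericMatrix xb, IntegerVector ia,
                   IntegerVector ib, double dmin, double k) {
  const int np = ia.size();
  double e = 0.0;
  NumericMatrix grad(xa.nrow(), 3);
  for (int p = 0; p < np; ++p) {
    int a = ia[p], b = ib[p];
    double dx = xa(a, 0) - xb(b, 0);
    double dy = xa(a, 1) - xb(b, 1);
    double dz = xa(a, 2) - xb(b, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d >= dmin || d <= 1e-9) continue;
    double t = dmin - d;
    e += k * t * t * t * t;
    double coef = -4.0 * k * t * t * t / d;
    grad(a, 0) += coef * dx; grad(a, 1) += coef * dy; grad(a, 2) += coef * dz;
  }
  return List::create(_["value"] = e, _["grad"] = grad);
}

// Full rigid-body pose score: rotate centred coordinates (z-y-x Euler,
// degrees), translate, trilinearly interpolate and return the weighted
// standardized sum.  One call per score evaluation keeps optimizer loops
// out of R.
// [[Rcpp::export]]
double cpp_pose_score(NumericVector values, IntegerVector dims,
                      NumericVector origin, NumericVector voxel,
                      NumericMatrix X0, NumericVector center,
                      NumericVector w, NumericVector pose,
                      double mean, double sd) {
  const double d2r = 3.14159265358979323846 / 180.0;
  double cx = std::cos(pose[0] * d2r), sx = std::sin(pose[0] * d2r);
  double cy = std::cos(pose[1] * d2r), sy = std::sin(pose[1] * d2r);
  double cz = std::cos(pose[2] * d2r), sz = std::sin(pose[2] * d2r);
  // R = Rz * Ry * Rx
  double r00 = cz * cy, r01 = cz * sy * sx - sz * cx, r02 = cz * sy * cx + sz * sx;
  double r10 = sz * cy, r11 = sz * sy * sx + cz * cx, r12 = sz * sy * cx - cz * sx;
  double r20 = -sy,     r21 = cy * sx,                r22 = cy * cx;
  double tx = center[0] + pose[3], ty = center[1] + pose[4], tz = center[2] + pose[5];
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = X0.nrow();
  double acc = 0.0;
  for (int p = 0; p < n; ++p) {
    double x0 = X0(p, 0), y0 = X0(p, 1), z0 = X0(p, 2);
    double px = r00 * x0 + r01 * y0 + r02 * z0 + tx;
    double py = r10 * x0 + r11 * y0 + r12 * z0 + ty;
    double pz = r20 * x0 + r21 * y0 + r22 * z0 + tz;
    double gx = (px - origin[0]) / voxel[0];
    double gy = (py - origin[1]) / voxel[1];
    double gz = (pz - origin[2]) / voxel[2];
    double v = 0.0;
    if (!(gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 ||
          gz > nz - 1)) {
      int ix = (int)gx, iy = (int)gy, iz = (int)gz;
      if (ix >= nx - 1) ix = nx - 2;
      if (iy >= ny - 1) iy = ny - 2;
      if (iz >= nz - 1) iz = nz - 2;
      double fx = gx - ix, fy = gy - iy, fz = gz - iz;
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            double ww = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) *
              (dz ? fz : 1 - fz);
            v += ww * values[idx3(ix + dx, iy + dy, iz + dz, nx, ny)];
          }
    }
    acc += w[p] * (v - mean);
  }
  return acc / sd;
}
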