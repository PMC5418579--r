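#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- cell-list helpers -----------------------------------------------------

struct CellList {
  double cell;
  double ox, oy, oz;
  int nx, ny, nz;
  std::unordered_map<int64_t, std::vector<int>> cells;

  int64_t key(int ix, int iy, int iz) const {
    return (static_cast<int64_t>(ix) * 73856093LL) ^
           (static_cast<int64_t>(iy) * 19349663LL) ^
           (static_cast<int64_t>(iz) * 83492791LL);
  }
  void build(const NumericMatrix &X, double cell_size) {
    cell = cell_size;
    ox = oy = oz = R_PosInf;
    for (int i = 0; i < X.nrow(); ++i) {
      ox = std::min(ox, X(i, 0));
      oy = std::min(oy, X(i, 1));
      oz = std::min(oz, X(i, 2));
    }
    for (int i = 0; i < X.nrow(); ++i) {
      int ix = (int)std::floor((X(i, 0) - ox) / cell);
      int iy = (int)std::floor((X(i, 1) - oy) / cell);
      int iz = (int)std::floor((X(i, 2) - oz) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
  template <typename F>
  void neighbours(double x, double y, double z, F f) const {
    int ix = (int)std::floor((x - ox) / cell);
    int iy = (int)std::floor((y - oy) / cell);
    int iz = (int)std::floor((z - oz) / cell);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int j : it->second) f(j);
        }
  }
};

// All cross pairs (i from A, j from B) with distance <= cutoff.
// [[Rcpp::export]]
DataFrame cpp_cross_pairs(NumericMatrix A, NumericMatrix B, double cutoff) {
  CellList cl;
  cl.build(B, cutoff);
  std::vector<int> ii, jj;
  std::vector<double> dd;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < A.nrow(); ++i) {
    cl.neighbours(A(i, 0), A(i, 1), A(i, 2), [&](int j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(std::sqrt(d2));
      }
    });
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["d"] = dd);
}

// Minimum distance between two coordinate sets (brute force).
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// ---- Shrake-Rupley SASA ----------------------------------------------------

// Deterministic golden-section spiral points on the unit sphere.
static void sphere_points(int n, std::vector<double> &px,
                          std::vector<double> &py, std::vector<double> &pz) {
  px.resize(n); py.resize(n); pz.resize(n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n; ++k) {
    double zc = 1.0 - 2.0 * (k + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - zc * zc));
    double th = ga * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = zc;
  }
}

// Per-atom solvent-accessible surface area, A^2.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix X, NumericVector radii, double probe,
                       int n_points) {
  int n = X.nrow();
  std::vector<double> px, py, pz;
  sphere_points(n_points, px, py, pz);
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  CellList cl;
  cl.build(X, 2.0 * (rmax + probe));
  NumericVector out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    double Ri = radii[i] + probe;
    nb.clear();
    cl.neighbours(X(i, 0), X(i, 1), X(i, 2), [&](int j) {
      if (j == i) return;
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
             dz = X(i, 2) - X(j, 2);
      double lim = Ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    });
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = X(i, 0) + Ri * px[k], qy = X(i, 1) + Ri * py[k],
             qz = X(i, 2) + Ri * pz[k];
      bool buried = false;
      for (int j : nb) {
        double Rj = radii[j] + probe;
        double dx = qx - X(j, 0), dy = qy - X(j, 1), dz = qz - X(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz, R2 = Rj * Rj;
        // points exactly on a neighbour's surface (coincident spheres) are
        // buried only for the higher-index atom: the shared surface counts once
        if (d2 < R2 - 1e-9 || (std::abs(d2 - R2) <= 1e-9 && j < i)) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * Ri * Ri * (double)acc / n_points;
  }
  return out;
}

// ---- Gaussian density rendering -------------------------------------------

// Splat atoms as isotropic Gaussians onto a (z fastest; dim nz,ny,nx) array.
// Values are scaled so that the plain sum over voxels equals the total weight
// (each Gaussian carries voxel^3 / ((2 pi)^{3/2} sigma^3)).
// [[Rcpp::export]]
NumericVector cpp_gaussian_splat(NumericMatrix X, NumericVector w,
                                 double sigma, NumericVector origin,
                                 double voxel, IntegerVector dims,
                                 double cut_sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(Dimension(nz, ny, nx));
  double norm = std::pow(voxel, 3) /
                (std::pow(2.0 * M_PI, 1.5) * std::pow(sigma, 3));
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double cut = cut_sigma * sigma;
  for (int a = 0; a < X.nrow(); ++a) {
    double cx = (X(a, 0) - origin[0]) / voxel;
    double cy = (X(a, 1) - origin[1]) / voxel;
    double cz = (X(a, 2) - origin[2]) / voxel;
    double cv = cut / voxel;
    int x0 = std::max(0, (int)std::ceil(cx - cv));
    int x1 = std::min(nx - 1, (int)std::floor(cx + cv));
    int y0 = std::max(0, (int)std::ceil(cy - cv));
    int y1 = std::min(ny - 1, (int)std::floor(cy + cv));
    int z0 = std::max(0, (int)std::ceil(cz - cv));
    int z1 = std::min(nz - 1, (int)std::floor(cz + cv));
    double amp = w[a] * norm;
    for (int ix = x0; ix <= x1; ++ix) {
      double ddx = (ix - cx) * voxel; double ex = ddx * ddx;
      for (int iy = y0; iy <= y1; ++iy) {
        double ddy = (iy - cy) * voxel; double exy = ex + ddy * ddy;
        for (int iz = z0; iz <= z1; ++iz) {
          double ddz = (iz - cz) * voxel;
          double r2 = exy + ddz * ddz;
          out[iz + (size_t)nz * (iy + (size_t)ny * ix)] +=
              amp * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}

// Trilinear interpolation of a (nz,ny,nx) array at fractional voxel
// coordinates P (columns x,y,z; 0-based). Points outside return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vals, IntegerVector dims,
                            NumericMatrix P, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = P.nrow();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    double x = P(k, 0), y = P(k, 1), z = P(k, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[k] = fill;
      continue;
    }
    int x0 = std::min((int)std::floor(x), nx - 2 >= 0 ? nx - 2 : 0);
    int y0 = std::min((int)std::floor(y), ny - 2 >= 0 ? ny - 2 : 0);
    int z0 = std::min((int)std::floor(z), nz - 2 >= 0 ? nz - 2 : 0);
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    auto at = [&](int ix, int iy, int iz) {
      if (ix >= nx) ix = nx - 1;
      if (iy >= ny) iy = ny - 1;
      if (iz >= nz) iz = nz - 1;
      return vals[iz + (size_t)nz * (iy + (size_t)ny * ix)];
    };
    double c00 = at(x0, y0, z0) * (1 - fx) + at(x0 + 1, y0, z0) * fx;
    double c10 = at(x0, y0 + 1, z0) * (1 - fx) + at(x0 + 1, y0 + 1, z0) * fx;
    double c01 = at(x0, y0, z0 + 1) * (1 - fx) + at(x0 + 1, y0, z0 + 1) * fx;
    double c11 = at(x0, y0 + 1, z0 + 1) * (1 - fx) + at(x0 + 1, y0 + 1, z0 + 1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[k] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
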