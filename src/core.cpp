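#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Arrays are R column-major 3D: linear index = x + nx*(y + ny*z), 0-based.
// Axis convention throughout: x left->right, y posterior->anterior, z inferior->superior.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// the 13 unique 3D direction pairs at Chebyshev distance 1
static const int DIR13[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

// ---------------------------------------------------------------------------
// connected components, connectivity 6 or 26, BFS
// [[Rcpp::export]]
IntegerVector cpp_cc_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> nbr;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        nbr.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<int> q;
  for (int idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++cur;
    lab[idx] = cur;
    q.push(idx);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
      for (auto &d : nbr) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int w = lin(xx, yy, zz, nx, ny);
        if (mask[w] && lab[w] == 0) { lab[w] = cur; q.push(w); }
      }
    }
  }
  lab.attr("n_components") = cur;
  return lab;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared, separable lower envelope),
// spacing-aware. Returns distance in mm from each TRUE voxel to the nearest
// FALSE voxel (FALSE voxels get 0). Voxels are treated as points at centers.
static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   double step) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double fq = f[q] + (double)q * q * step * step;
      double fv = f[v[k]] + (double)v[k] * v[k] * step * step;
      s = (fq - fv) / (2.0 * step * step * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * step;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  const double INF = 1e30;
  NumericVector g(n);
  for (int i = 0; i < n; ++i) g[i] = mask[i] ? INF : 0.0;
  // pass along x
  {
    std::vector<double> f(nx), d(nx);
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
      edt_1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
    }
  }
  {
    std::vector<double> f(ny), d(ny);
    for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
      edt_1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
    }
  }
  {
    std::vector<double> f(nz), d(nz);
    for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
      edt_1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = std::sqrt(d[z]);
    }
  }
  return g;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis (0=x,1=y,2=z).
// boundary: 0 = replicate edge, 1 = periodic wrap.
// Kernel applied as out[i] = sum_k ker[k] * in[i + k - off].
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector arr, IntegerVector dim,
                            NumericVector kernel, int axis, int boundary) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nk = kernel.size(), off = nk / 2;
  NumericVector out(arr.size());
  int nax = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(nax), res(nax);
  int n1 = (axis == 0) ? ny : nx;
  int n2 = (axis == 2) ? ny : nz;
  for (int b = 0; b < n2; ++b) for (int a = 0; a < n1; ++a) {
    for (int i = 0; i < nax; ++i) {
      int x = (axis == 0) ? i : a, y = (axis == 1) ? i : ((axis == 0) ? a : b);
      int z = (axis == 2) ? i : b;
      line[i] = arr[lin(x, y, z, nx, ny)];
    }
    for (int i = 0; i < nax; ++i) {
      double s = 0;
      for (int k = 0; k < nk; ++k) {
        int j = i + k - off;
        if (boundary == 1) { j = ((j % nax) + nax) % nax; }
        else { if (j < 0) j = 0; if (j >= nax) j = nax - 1; }
        s += kernel[k] * line[j];
      }
      res[i] = s;
    }
    for (int i = 0; i < nax; ++i) {
      int x = (axis == 0) ? i : a, y = (axis == 1) ? i : ((axis == 0) ? a : b);
      int z = (axis == 2) ? i : b;
      out[lin(x, y, z, nx, ny)] = res[i];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear / nearest resampling onto an isotropic-style grid.
// Output voxel center i maps to input index coordinate i * target / spacing.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector arr, IntegerVector dim,
                           NumericVector spacing, NumericVector target,
                           IntegerVector outdim, bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((double)ox * oy * oz);
  double sx = target[0] / spacing[0], sy = target[1] / spacing[1], sz = target[2] / spacing[2];
  for (int z = 0; z < oz; ++z) for (int y = 0; y < oy; ++y) for (int x = 0; x < ox; ++x) {
    double fx = x * sx, fy = y * sy, fz = z * sz;
    if (fx < 0) fx = 0; if (fy < 0) fy = 0; if (fz < 0) fz = 0;
    if (fx > nx - 1) fx = nx - 1; if (fy > ny - 1) fy = ny - 1; if (fz > nz - 1) fz = nz - 1;
    double val;
    if (nearest) {
      int ix = (int)std::lround(fx), iy = (int)std::lround(fy), iz = (int)std::lround(fz);
      val = arr[lin(ix, iy, iz, nx, ny)];
    } else {
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
      int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
      double tx = fx - x0, ty = fy - y0, tz = fz - z0;
      double c00 = arr[lin(x0,y0,z0,nx,ny)] * (1-tx) + arr[lin(x1,y0,z0,nx,ny)] * tx;
      double c10 = arr[lin(x0,y1,z0,nx,ny)] * (1-tx) + arr[lin(x1,y1,z0,nx,ny)] * tx;
      double c01 = arr[lin(x0,y0,z1,nx,ny)] * (1-tx) + arr[lin(x1,y0,z1,nx,ny)] * tx;
      double c11 = arr[lin(x0,y1,z1,nx,ny)] * (1-tx) + arr[lin(x1,y1,z1,nx,ny)] * tx;
      double c0 = c00 * (1-ty) + c10 * ty, c1 = c01 * (1-ty) + c11 * ty;
      val = c0 * (1-tz) + c1 * tz;
    }
    out[lin(x, y, z, ox, oy)] = val;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Texture matrices. `levels` holds integer gray levels 1..ngray inside the
// region and 0 outside; the array is a cropped bounding box of one region.

// GLCM: symmetric co-occurrence counts per direction; ngray x ngray x 13
// [[Rcpp::export]]
NumericVector cpp_glcm13(IntegerVector levels, IntegerVector dim, int ngray) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((double)ngray * ngray * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      int li = levels[lin(x, y, z, nx, ny)];
      if (li == 0) continue;
      int xx = x + dx, yy = y + dy, zz = z + dz;
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int lj = levels[lin(xx, yy, zz, nx, ny)];
      if (lj == 0) continue;
      out[(li - 1) + ngray * ((lj - 1) + ngray * d)] += 1.0;
      out[(lj - 1) + ngray * ((li - 1) + ngray * d)] += 1.0;
    }
  }
  out.attr("dim") = IntegerVector::create(ngray, ngray, 13);
  return out;
}

// GLRLM: run-length counts per direction; ngray x maxrun x 13
// [[Rcpp::export]]
NumericVector cpp_glrlm13(IntegerVector levels, IntegerVector dim, int ngray) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxrun = std::max(nx, std::max(ny, nz));
  NumericVector out((double)ngray * maxrun * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
      int li = levels[lin(x, y, z, nx, ny)];
      if (li == 0) continue;
      // run start: predecessor out of bounds, outside region, or different level
      int px = x - dx, py = y - dy, pz = z - dz;
      bool start = true;
      if (px >= 0 && py >= 0 && pz >= 0 && px < nx && py < ny && pz < nz) {
        if (levels[lin(px, py, pz, nx, ny)] == li) start = false;
      }
      if (!start) continue;
      int len = 1;
      int xx = x + dx, yy = y + dy, zz = z + dz;
      while (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz &&
             levels[lin(xx, yy, zz, nx, ny)] == li) {
        ++len; xx += dx; yy += dy; zz += dz;
      }
      out[(li - 1) + ngray * ((len - 1) + maxrun * d)] += 1.0;
    }
  }
  out.attr("dim") = IntegerVector::create(ngray, maxrun, 13);
  return out;
}

// GLSZM zones: 26-connected components of constant gray level.
// Returns a matrix (n_zones x 2): gray level, zone size.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs;
  std::queue<int> q;
  for (int idx = 0; idx < n; ++idx) {
    if (levels[idx] == 0 || seen[idx]) continue;
    int gl = levels[idx], size = 0;
    seen[idx] = 1; q.push(idx);
    while (!q.empty()) {
      int v = q.front(); q.pop(); ++size;
      int z = v / (nx * ny), r = v % (nx * ny), y = r / nx, x = r % nx;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int w = lin(xx, yy, zz, nx, ny);
        if (!seen[w] && levels[w] == gl) { seen[w] = 1; q.push(w); }
      }
    }
    zl.push_back(gl); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) { out(i, 0) = zl[i]; out(i, 1) = zs[i]; }
  return out;
}

// GLDM: dependence matrix; j = 1 + number of 26-neighbours within |diff| <= alpha.
// ngray x 27 counts.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dim, int ngray, int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ngray, 27);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int li = levels[lin(x, y, z, nx, ny)];
    if (li == 0) continue;
    int dep = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int xx = x + dx, yy = y + dy, zz = z + dz;
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int lj = levels[lin(xx, yy, zz, nx, ny)];
      if (lj == 0) continue;
      if (std::abs(lj - li) <= alpha) ++dep;
    }
    out(li - 1, dep) += 1.0;
  }
  return out;
}

// NGTDM: per gray level i, n_i (count) and s_i (sum |i - mean of valid neighbours|).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ngray) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ngray, 2); // col 0: n_i, col 1: s_i
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int li = levels[lin(x, y, z, nx, ny)];
    if (li == 0) continue;
    double sum = 0; int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int xx = x + dx, yy = y + dy, zz = z + dz;
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int lj = levels[lin(xx, yy, zz, nx, ny)];
      if (lj == 0) continue;
      sum += lj; ++cnt;
    }
    out(li - 1, 0) += 1.0;
    if (cnt > 0) out(li - 1, 1) += std::fabs((double)li - sum / cnt);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Maximum pairwise diameters from boundary voxel coordinates (0-based, n x 3),
// in mm. Returns (max3D, axial [fixed z], coronal [fixed y], sagittal [fixed x]).
// [[Rcpp::export]]
NumericVector cpp_max_diameters(IntegerMatrix coords, NumericVector spacing) {
  int n = coords.nrow();
  double m3 = 0, mz = 0, my = 0, mx = 0;
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double dx = (coords(i,0) - coords(j,0)) * spacing[0];
    double dy = (coords(i,1) - coords(j,1)) * spacing[1];
    double dz = (coords(i,2) - coords(j,2)) * spacing[2];
    double d2 = dx*dx + dy*dy + dz*dz;
    if (d2 > m3) m3 = d2;
    if (coords(i,2) == coords(j,2)) { double d = dx*dx + dy*dy; if (d > mz) mz = d; }
    if (coords(i,1) == coords(j,1)) { double d = dx*dx + dz*dz; if (d > my) my = d; }
    if (coords(i,0) == coords(j,0)) { double d = dy*dy + dz*dz; if (d > mx) mx = d; }
  }
  return NumericVector::create(std::sqrt(m3), std::sqrt(mz), std::sqrt(my), std::sqrt(mx));
}
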