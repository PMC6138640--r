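// 3D raster primitives shared by the segmentation and morphometry stages.
// Arrays are indexed (z, y, x) with dim = c(nz, ny, nx); R's column-major
// layout means index = z + nz*(y + ny*x).
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline R_xlen_t idx3(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

// ---- separable Gaussian blur, reflective boundaries, sigma in voxels ----

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &v : k) v /= s;
  return k;
}

// reflect index into [0, n-1] (mirror without repeating the edge sample
// would be 'reflect_101'; plain mirror conserves mass better for masks)
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// 1D convolution of a line with reflective boundaries
static void conv_line(const double *in, double *out, int n,
                      const std::vector<double> &k, int r) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    if (i >= r && i + r < n) {
      const double *p = in + i - r;
      for (int t = 0; t < 2 * r + 1; ++t) acc += k[t] * p[t];
    } else {
      for (int t = -r; t <= r; ++t) acc += k[t + r] * in[reflect(i + t, n)];
    }
    out[i] = acc;
  }
}

// [[Rcpp::export(name = ".cpp_blur3d")]]
NumericVector cpp_blur3d(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> buf(vol.begin(), vol.end());
  std::vector<double> line, lout;
  // z pass (contiguous lines)
  if (sigma[0] > 0) {
    std::vector<double> k = gauss_kernel(sigma[0]);
    int r = ((int)k.size() - 1) / 2;
    lout.resize(nz);
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        double *p = buf.data() + idx3(0, y, x, nz, ny);
        conv_line(p, lout.data(), nz, k, r);
        std::copy(lout.begin(), lout.end(), p);
      }
  }
  // y pass
  if (sigma[1] > 0) {
    std::vector<double> k = gauss_kernel(sigma[1]);
    int r = ((int)k.size() - 1) / 2;
    line.resize(ny); lout.resize(ny);
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) line[y] = buf[idx3(z, y, x, nz, ny)];
        conv_line(line.data(), lout.data(), ny, k, r);
        for (int y = 0; y < ny; ++y) buf[idx3(z, y, x, nz, ny)] = lout[y];
      }
  }
  // x pass
  if (sigma[2] > 0) {
    std::vector<double> k = gauss_kernel(sigma[2]);
    int r = ((int)k.size() - 1) / 2;
    line.resize(nx); lout.resize(nx);
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        for (int x = 0; x < nx; ++x) line[x] = buf[idx3(z, y, x, nz, ny)];
        conv_line(line.data(), lout.data(), nx, k, r);
        for (int x = 0; x < nx; ++x) buf[idx3(z, y, x, nz, ny)] = lout[x];
      }
  }
  NumericVector res(buf.begin(), buf.end());
  res.attr("dim") = dim;
  return res;
}

// ---- 6-connected component labelling ----

// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i]) continue;
        ++cur;
        stack.push_back(i);
        lab[i] = cur;
        while (!stack.empty()) {
          R_xlen_t j = stack.back(); stack.pop_back();
          int xz = (int)(j % nz);
          int xy = (int)((j / nz) % ny);
          int xx = (int)(j / ((R_xlen_t)nz * ny));
          for (int d = 0; d < 6; ++d) {
            int z2 = xz + dz[d], y2 = xy + dy[d], x2 = xx + dx[d];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
            R_xlen_t j2 = idx3(z2, y2, x2, nz, ny);
            if (mask[j2] && !lab[j2]) { lab[j2] = cur; stack.push_back(j2); }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// ---- 3D hole fill: background connected to the border stays background ----

// [[Rcpp::export(name = ".cpp_fill_holes3d")]]
LogicalVector cpp_fill_holes3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<char> outside(n, 0);
  std::vector<R_xlen_t> stack;
  const int dz[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, 1, -1};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
        R_xlen_t i = idx3(z, y, x, nz, ny);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  while (!stack.empty()) {
    R_xlen_t j = stack.back(); stack.pop_back();
    int xz = (int)(j % nz);
    int xy = (int)((j / nz) % ny);
    int xx = (int)(j / ((R_xlen_t)nz * ny));
    for (int d = 0; d < 6; ++d) {
      int z2 = xz + dz[d], y2 = xy + dy[d], x2 = xx + dx[d];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
      R_xlen_t j2 = idx3(z2, y2, x2, nz, ny);
      if (!mask[j2] && !outside[j2]) { outside[j2] = 1; stack.push_back(j2); }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// ---- anisotropic Euclidean distance transform (Felzenszwalb-Huttenlocher) --

static void dt1d(const double *f, double *d, int n, double w2) {
  // squared distance transform of sampled function f on grid step sqrt(w2)
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// distance (um) from every voxel to the nearest TRUE voxel
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  const double INF = 1e30;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;
  std::vector<double> line, dline;
  // z pass
  line.resize(nz); dline.resize(nz);
  double wz2 = spacing[0] * spacing[0];
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) line[z] = g[idx3(z, y, x, nz, ny)];
      dt1d(line.data(), dline.data(), nz, wz2);
      for (int z = 0; z < nz; ++z) g[idx3(z, y, x, nz, ny)] = dline[z];
    }
  // y pass
  line.resize(ny); dline.resize(ny);
  double wy2 = spacing[1] * spacing[1];
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) line[y] = g[idx3(z, y, x, nz, ny)];
      dt1d(line.data(), dline.data(), ny, wy2);
      for (int y = 0; y < ny; ++y) g[idx3(z, y, x, nz, ny)] = dline[y];
    }
  // x pass
  line.resize(nx); dline.resize(nx);
  double wx2 = spacing[2] * spacing[2];
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) line[x] = g[idx3(z, y, x, nz, ny)];
      dt1d(line.data(), dline.data(), nx, wx2);
      for (int x = 0; x < nx; ++x) g[idx3(z, y, x, nz, ny)] = dline[x];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i] < 0 ? 0 : g[i]);
  out.attr("dim") = dim;
  return out;
}

// ---- isosurface triangulation by marching tetrahedra ----
// Each cube is split into 6 tetrahedra sharing the main diagonal; per
// tetrahedron the level crossing yields 0, 1 or 2 triangles with vertices
// linearly interpolated along edges. Returns an ntri x 9 matrix of physical
// (z,y,x) coordinates for the three vertices of each triangle.

struct V3 { double z, y, x; };

static inline V3 vinterp(const V3 &a, const V3 &b, double va, double vb, double level) {
  double t = (level - va) / (vb - va);
  V3 r;
  r.z = a.z + t * (b.z - a.z);
  r.y = a.y + t * (b.y - a.y);
  r.x = a.x + t * (b.x - a.x);
  return r;
}

// [[Rcpp::export(name = ".cpp_march_tet")]]
NumericMatrix cpp_march_tet(NumericVector vol, IntegerVector dim,
                            NumericVector spacing, double level) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  // cube corner offsets (z,y,x)
  const int co[8][3] = {
    {0,0,0},{0,0,1},{0,1,1},{0,1,0},{1,0,0},{1,0,1},{1,1,1},{1,1,0}};
  // 6 tetrahedra all containing the diagonal corner0-corner6
  const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::vector<double> tri;
  tri.reserve(1 << 16);
  double cv[8];
  V3 cp[8];
  auto push_tri = [&](const V3 &a, const V3 &b, const V3 &c) {
    tri.push_back(a.z); tri.push_back(a.y); tri.push_back(a.x);
    tri.push_back(b.z); tri.push_back(b.y); tri.push_back(b.x);
    tri.push_back(c.z); tri.push_back(c.y); tri.push_back(c.x);
  };
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int zz = z + co[c][0], yy = y + co[c][1], xx = x + co[c][2];
          cv[c] = vol[idx3(zz, yy, xx, nz, ny)];
          cp[c].z = zz * dz; cp[c].y = yy * dy; cp[c].x = xx * dx;
          if (cv[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int k = 0; k < 4; ++k) {
            if (cv[vi[k]] >= level) in[nin++] = vi[k]; else out[nout++] = vi[k];
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            int base[3];
            int nb = 0;
            for (int k = 0; k < 4; ++k)
              if (vi[k] != apex) base[nb++] = vi[k];
            V3 p0 = vinterp(cp[apex], cp[base[0]], cv[apex], cv[base[0]], level);
            V3 p1 = vinterp(cp[apex], cp[base[1]], cv[apex], cv[base[1]], level);
            V3 p2 = vinterp(cp[apex], cp[base[2]], cv[apex], cv[base[2]], level);
            push_tri(p0, p1, p2);
          } else { // 2 in, 2 out -> quad
            V3 p0 = vinterp(cp[in[0]], cp[out[0]], cv[in[0]], cv[out[0]], level);
            V3 p1 = vinterp(cp[in[0]], cp[out[1]], cv[in[0]], cv[out[1]], level);
            V3 p2 = vinterp(cp[in[1]], cp[out[1]], cv[in[1]], cv[out[1]], level);
            V3 p3 = vinterp(cp[in[1]], cp[out[0]], cv[in[1]], cv[out[0]], level);
            push_tri(p0, p1, p2);
            push_tri(p0, p2, p3);
          }
        }
      }
  int ntri = (int)(tri.size() / 9);
  NumericMatrix m(ntri, 9);
  for (int i = 0; i < ntri; ++i)
    for (int j = 0; j < 9; ++j)
      m(i, j) = tri[(R_xlen_t)i * 9 + j];
  return m;
}

// trilinear interpolation of a (z,y,x) field at physical points (um)
// [[Rcpp::export(name = ".cpp_interp3")]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericVector spacing, NumericMatrix pts) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int np = pts.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double fz = pts(i, 0) / spacing[0];
    double fy = pts(i, 1) / spacing[1];
    double fx = pts(i, 2) / spacing[2];
    int z0 = (int)std::floor(fz), y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
    double tz = fz - z0, ty = fy - y0, tx = fx - x0;
    if (z0 < 0) { z0 = 0; tz = 0; }
    if (y0 < 0) { y0 = 0; ty = 0; }
    if (x0 < 0) { x0 = 0; tx = 0; }
    if (z0 >= nz - 1) { z0 = nz - 2 >= 0 ? nz - 2 : 0; tz = nz > 1 ? 1.0 : 0.0; }
    if (y0 >= ny - 1) { y0 = ny - 2 >= 0 ? ny - 2 : 0; ty = ny > 1 ? 1.0 : 0.0; }
    if (x0 >= nx - 1) { x0 = nx - 2 >= 0 ? nx - 2 : 0; tx = nx > 1 ? 1.0 : 0.0; }
    int z1 = nz > 1 ? z0 + 1 : z0, y1 = ny > 1 ? y0 + 1 : y0, x1 = nx > 1 ? x0 + 1 : x0;
    double c000 = vol[idx3(z0, y0, x0, nz, ny)], c001 = vol[idx3(z0, y0, x1, nz, ny)];
    double c010 = vol[idx3(z0, y1, x0, nz, ny)], c011 = vol[idx3(z0, y1, x1, nz, ny)];
    double c100 = vol[idx3(z1, y0, x0, nz, ny)], c101 = vol[idx3(z1, y0, x1, nz, ny)];
    double c110 = vol[idx3(z1, y1, x0, nz, ny)], c111 = vol[idx3(z1, y1, x1, nz, ny)];
    double c00 = c000 * (1 - tx) + c001 * tx;
    double c01 = c010 * (1 - tx) + c011 * tx;
    double c10 = c100 * (1 - tx) + c101 * tx;
    double c11 = c110 * (1 - tx) + c111 * tx;
    double c0 = c00 * (1 - ty) + c01 * ty;
    double c1 = c10 * (1 - ty) + c11 * ty;
    out[i] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}
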