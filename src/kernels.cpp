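// Low-level 3D image kernels. All arrays are R numeric/integer/logical
// vectors in column-major (x fastest) order with explicit dims, matching
// base R array layout. Boundary handling: reflection for filtering,
// clamp-or-fill for resampling.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // mirror without repeating the edge sample twice beyond necessity
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable Gaussian smoothing with a truncated (4 sigma) kernel.
// [[Rcpp::export(name = ".gauss_smooth3")]]
NumericVector gauss_smooth3(NumericVector img, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double &v : k) v /= s;

  NumericVector a = clone(img);
  NumericVector b(n);
  const int dims[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    const int nA = dims[ax];
    const R_xlen_t sA = stride[ax];
    // iterate over all lines along axis ax
    const int nB = dims[(ax + 1) % 3], nC = dims[(ax + 2) % 3];
    const R_xlen_t sB = stride[(ax + 1) % 3], sC = stride[(ax + 2) % 3];
    for (int c = 0; c < nC; ++c) {
      for (int bI = 0; bI < nB; ++bI) {
        const R_xlen_t base = (R_xlen_t)bI * sB + (R_xlen_t)c * sC;
        for (int i = 0; i < nA; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j)
            acc += k[j + r] * a[base + (R_xlen_t)reflect(i + j, nA) * sA];
          b[base + (R_xlen_t)i * sA] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  a.attr("dim") = dim;
  return a;
}

static inline double sample_trilinear(const double *img, int nx, int ny, int nz,
                                      double x, double y, double z,
                                      double fill, bool has_fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    if (has_fill) return fill;
    // clamp
    x = std::min(std::max(x, 0.0), (double)(nx - 1));
    y = std::min(std::max(y, 0.0), (double)(ny - 1));
    z = std::min(std::max(z, 0.0), (double)(nz - 1));
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1), z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  double c000 = img[x0 + y0 * sy + z0 * sz], c100 = img[x1 + y0 * sy + z0 * sz];
  double c010 = img[x0 + y1 * sy + z0 * sz], c110 = img[x1 + y1 * sy + z0 * sz];
  double c001 = img[x0 + y0 * sy + z1 * sz], c101 = img[x1 + y0 * sy + z1 * sz];
  double c011 = img[x0 + y1 * sy + z1 * sz], c111 = img[x1 + y1 * sy + z1 * sz];
  double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Pull-back warp: out(i) = img(i + u(i)), u in voxel units on the output grid.
// nearest = true uses nearest-neighbour (labels); fill used outside the grid.
// [[Rcpp::export(name = ".warp_pullback3")]]
NumericVector warp_pullback3(NumericVector img, IntegerVector dim,
                             NumericVector ux, NumericVector uy, NumericVector uz,
                             double fill, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  const double *p = img.begin();
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        double sx = x + ux[idx], sy = y + uy[idx], sz = z + uz[idx];
        if (nearest) {
          long ix = std::lround(sx), iy = std::lround(sy), iz = std::lround(sz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
            out[idx] = fill;
          else
            out[idx] = p[ix + iy * (R_xlen_t)nx + iz * (R_xlen_t)nx * ny];
        } else {
          out[idx] = sample_trilinear(p, nx, ny, nz, sx, sy, sz, fill, true);
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Resample img (dimIn) onto a grid of dimOut assuming aligned corners-to-extent:
// input coordinate = out_index * (nIn-1)/(nOut-1) per axis (clamped edges).
// [[Rcpp::export(name = ".resample3")]]
NumericVector resample3(NumericVector img, IntegerVector dimIn, IntegerVector dimOut,
                        bool nearest) {
  const int nx = dimIn[0], ny = dimIn[1], nz = dimIn[2];
  const int mx = dimOut[0], my = dimOut[1], mz = dimOut[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double *p = img.begin();
  double rx = mx > 1 ? (double)(nx - 1) / (mx - 1) : 0.0;
  double ry = my > 1 ? (double)(ny - 1) / (my - 1) : 0.0;
  double rz = mz > 1 ? (double)(nz - 1) / (mz - 1) : 0.0;
  R_xlen_t idx = 0;
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x, ++idx) {
        double sx = x * rx, sy = y * ry, sz = z * rz;
        if (nearest) {
          long ix = std::lround(sx), iy = std::lround(sy), iz = std::lround(sz);
          out[idx] = p[ix + iy * (R_xlen_t)nx + iz * (R_xlen_t)nx * ny];
        } else {
          out[idx] = sample_trilinear(p, nx, ny, nz, sx, sy, sz, 0.0, false);
        }
      }
  out.attr("dim") = dimOut;
  return out;
}

// 6-connected component labelling of a logical mask; labels 1..K by discovery
// order (deterministic: raster scan + BFS).
// [[Rcpp::export(name = ".label_components3")]]
IntegerVector label_components3(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / sz);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t j = xx + yy * sy + (R_xlen_t)zz * sz;
        if (mask[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Binary dilation (erode via complement in R) with an arbitrary offset list
// (K x 3 integer matrix of voxel offsets). Out-of-grid neighbours are ignored.
// [[Rcpp::export(name = ".binary_dilate3")]]
LogicalVector binary_dilate3(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
  const int K = offsets.nrow();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / sz);
    for (int k = 0; k < K; ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      out[xx + yy * sy + (R_xlen_t)zz * sz] = true;
    }
  }
  out.attr("dim") = dim;
  return out;
}
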