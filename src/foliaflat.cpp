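#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// trilinear sample in voxel-index space (0-based), coordinates clamped to grid
static double trilinear_idx(const double *v, int nx, int ny, int nz,
                            double x, double y, double z) {
  x = clampd(x, 0.0, nx - 1.0);
  y = clampd(y, 0.0, ny - 1.0);
  z = clampd(z, 0.0, nz - 1.0);
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2;
  if (j0 > ny - 2) j0 = ny - 2;
  if (k0 > nz - 2) k0 = nz - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  size_t s = (size_t)nx, sy = (size_t)nx * ny;
  const double *p = v + i0 + s * j0 + sy * k0;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[s] * (1 - fx) + p[s + 1] * fx;
  double c01 = p[sy] * (1 - fx) + p[sy + 1] * fx;
  double c11 = p[sy + s] * (1 - fx) + p[sy + s + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = pts.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  for (int i = 0; i < n; ++i)
    out[i] = trilinear_idx(v, nx, ny, nz, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// separable Gaussian smoothing along one axis, reflecting boundary
static void smooth_axis(std::vector<double> &a, int nx, int ny, int nz,
                        int axis, const std::vector<double> &ker) {
  int r = (int)ker.size() / 2;
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx : (size_t)nx * ny);
  std::vector<double> buf(n);
  int d1 = axis == 0 ? ny : nx;
  int d2 = axis == 2 ? ny : nz;
  for (int b = 0; b < d2; ++b) {
    for (int a1 = 0; a1 < d1; ++a1) {
      size_t base;
      if (axis == 0) base = (size_t)nx * a1 + (size_t)nx * ny * b;
      else if (axis == 1) base = a1 + (size_t)nx * ny * b;
      else base = a1 + (size_t)nx * b;
      for (int i = 0; i < n; ++i) buf[i] = a[base + stride * i];
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int k = -r; k <= r; ++k) {
          int j = i + k;
          if (j < 0) j = -j;                 // reflect
          if (j > n - 1) j = 2 * (n - 1) - j;
          s += ker[k + r] * buf[clampi(j, 0, n - 1)];
        }
        a[base + stride * i] = s;
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto &x : k) x /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> ker = gauss_kernel(sigma);
  smooth_axis(a, nx, ny, nz, 0, ker);
  smooth_axis(a, nx, ny, nz, 1, ker);
  smooth_axis(a, nx, ny, nz, 2, ker);
  return NumericVector(a.begin(), a.end());
}

// Jacobi eigen decomposition of a symmetric 3x3 matrix.
// On return eval sorted descending, evec columns matching.
static void eigen3(double m[3][3], double eval[3], double evec[3][3]) {
  double a[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      a[i][j] = m[i][j];
      evec[i][j] = (i == j) ? 1.0 : 0.0;
    }
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-18) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = evec[k][p], vkq = evec[k][q];
          evec[k][p] = c * vkp - s * vkq;
          evec[k][q] = s * vkp + c * vkq;
        }
      }
  }
  int ord[3] = {0, 1, 2};
  double d[3] = {a[0][0], a[1][1], a[2][2]};
  std::sort(ord, ord + 3, [&](int i, int j) { return d[i] > d[j]; });
  double tmpv[3][3];
  for (int c = 0; c < 3; ++c) {
    eval[c] = d[ord[c]];
    for (int r = 0; r < 3; ++r) tmpv[r][c] = evec[r][ord[c]];
  }
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) evec[r][c] = tmpv[r][c];
}

// Oriented anisotropic filter: 2D Gaussian smoothing restricted to the
// plane of least brightness variation (two smallest structure-tensor
// eigenvectors), sampled on a window^3 neighborhood with trilinear
// interpolation; near-isotropic tensors fall back to an isotropic 3D
// Gaussian of the same FWHM.
// [[Rcpp::export]]
NumericVector cpp_oriented_smooth(NumericVector vol, IntegerVector dim,
                                  int window, double fwhm,
                                  double tensorSigma, double isoRatio) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  const double *v = vol.begin();
  double sg = fwhm / 2.354820045; // FWHM -> sigma, in voxels
  int h = window / 2;

  // gradients (central differences, clamped) -> tensor products
  std::vector<double> gxx(nvox), gyy(nvox), gzz(nvox), gxy(nvox), gxz(nvox),
      gyz(nvox);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + (size_t)nx * j + (size_t)nx * ny * k;
        double gx = 0.5 * (v[clampi(i + 1, 0, nx - 1) + (size_t)nx * j + (size_t)nx * ny * k] -
                           v[clampi(i - 1, 0, nx - 1) + (size_t)nx * j + (size_t)nx * ny * k]);
        double gy = 0.5 * (v[i + (size_t)nx * clampi(j + 1, 0, ny - 1) + (size_t)nx * ny * k] -
                           v[i + (size_t)nx * clampi(j - 1, 0, ny - 1) + (size_t)nx * ny * k]);
        double gz = 0.5 * (v[i + (size_t)nx * j + (size_t)nx * ny * clampi(k + 1, 0, nz - 1)] -
                           v[i + (size_t)nx * j + (size_t)nx * ny * clampi(k - 1, 0, nz - 1)]);
        gxx[id] = gx * gx; gyy[id] = gy * gy; gzz[id] = gz * gz;
        gxy[id] = gx * gy; gxz[id] = gx * gz; gyz[id] = gy * gz;
      }
  std::vector<double> ker = gauss_kernel(tensorSigma);
  for (auto *c : {&gxx, &gyy, &gzz, &gxy, &gxz, &gyz}) {
    smooth_axis(*c, nx, ny, nz, 0, ker);
    smooth_axis(*c, nx, ny, nz, 1, ker);
    smooth_axis(*c, nx, ny, nz, 2, ker);
  }

  // isotropic-fallback weights on the integer window
  std::vector<double> wiso((size_t)window * window * window);
  {
    double s = 0;
    int id = 0;
    for (int c = -h; c <= h; ++c)
      for (int b = -h; b <= h; ++b)
        for (int a = -h; a <= h; ++a, ++id) {
          wiso[id] = std::exp(-0.5 * (a * a + b * b + c * c) / (sg * sg));
          s += wiso[id];
        }
    for (auto &x : wiso) x /= s;
  }
  // in-plane weights on the 2D window
  std::vector<double> w2((size_t)window * window);
  {
    int id = 0;
    for (int b = -h; b <= h; ++b)
      for (int a = -h; a <= h; ++a, ++id)
        w2[id] = std::exp(-0.5 * (a * a + b * b) / (sg * sg));
  }

  NumericVector out((R_xlen_t)nvox);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + (size_t)nx * j + (size_t)nx * ny * k;
        double m[3][3] = {{gxx[id], gxy[id], gxz[id]},
                          {gxy[id], gyy[id], gyz[id]},
                          {gxz[id], gyz[id], gzz[id]}};
        double eval[3], evec[3][3];
        eigen3(m, eval, evec);
        bool iso = eval[0] <= 0 || eval[0] < isoRatio * std::max(eval[1], 0.0) ||
                   eval[0] < 1e-12;
        double acc = 0.0;
        if (iso) {
          int id2 = 0;
          for (int c = -h; c <= h; ++c)
            for (int b = -h; b <= h; ++b)
              for (int a = -h; a <= h; ++a, ++id2) {
                int ii = clampi(i + a, 0, nx - 1);
                int jj = clampi(j + b, 0, ny - 1);
                int kk = clampi(k + c, 0, nz - 1);
                acc += wiso[id2] * v[ii + (size_t)nx * jj + (size_t)nx * ny * kk];
              }
          out[id] = acc;
        } else {
          double e2x = evec[0][1], e2y = evec[1][1], e2z = evec[2][1];
          double e3x = evec[0][2], e3y = evec[1][2], e3z = evec[2][2];
          double wsum = 0.0;
          int id2 = 0;
          for (int b = -h; b <= h; ++b)
            for (int a = -h; a <= h; ++a, ++id2) {
              double x = i + a * e2x + b * e3x;
              double y = j + a * e2y + b * e3y;
              double z = k + a * e2z + b * e3z;
              double val = trilinear_idx(v, nx, ny, nz, x, y, z);
              acc += w2[id2] * val;
              wsum += w2[id2];
            }
          out[id] = acc / wsum;
        }
      }
  return out;
}

// 6-connected component labelling of a logical mask
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab((R_xlen_t)nvox);
  std::vector<size_t> stack;
  int cur = 0;
  const int *m = mask.begin();
  for (size_t s = 0; s < nvox; ++s) {
    if (!m[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t t = stack.back();
      stack.pop_back();
      int i = t % nx, j = (t / nx) % ny, k = t / ((size_t)nx * ny);
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t u = ii + (size_t)nx * jj + (size_t)nx * ny * kk;
        if (m[u] && !lab[u]) {
          lab[u] = cur;
          stack.push_back(u);
        }
      }
    }
  }
  return lab;
}

// fill interior cavities: background voxels not 6-connected to the border
// become foreground
// [[Rcpp::export]]
LogicalVector cpp_fill_cavities(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<char> reach(nvox, 0);
  std::vector<size_t> stack;
  const int *m = mask.begin();
  auto push = [&](int i, int j, int k) {
    size_t u = i + (size_t)nx * j + (size_t)nx * ny * k;
    if (!m[u] && !reach[u]) {
      reach[u] = 1;
      stack.push_back(u);
    }
  };
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) {
      push(0, j, k);
      push(nx - 1, j, k);
    }
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) {
      push(i, 0, k);
      push(i, ny - 1, k);
    }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) {
      push(i, j, 0);
      push(i, j, nz - 1);
    }
  while (!stack.empty()) {
    size_t t = stack.back();
    stack.pop_back();
    int i = t % nx, j = (t / nx) % ny, k = t / ((size_t)nx * ny);
    const int di[6] = {1, -1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, 1, -1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, 1, -1};
    for (int d = 0; d < 6; ++d) {
      int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      push(ii, jj, kk);
    }
  }
  LogicalVector out((R_xlen_t)nvox);
  for (size_t s = 0; s < nvox; ++s) out[s] = m[s] || !reach[s];
  return out;
}

// ---- triangle-triangle intersection (transversal crossings; coplanar
// overlaps are not flagged, which is adequate for generic meshes) ----

static bool seg_tri_intersect(const double *p, const double *q,
                              const double *a, const double *b,
                              const double *c) {
  double u[3], vv[3], n[3], dir[3], w0[3];
  for (int i = 0; i < 3; ++i) {
    u[i] = b[i] - a[i];
    vv[i] = c[i] - a[i];
    dir[i] = q[i] - p[i];
    w0[i] = p[i] - a[i];
  }
  n[0] = u[1] * vv[2] - u[2] * vv[1];
  n[1] = u[2] * vv[0] - u[0] * vv[2];
  n[2] = u[0] * vv[1] - u[1] * vv[0];
  double denom = n[0] * dir[0] + n[1] * dir[1] + n[2] * dir[2];
  if (std::fabs(denom) < 1e-14) return false; // parallel / coplanar
  double t = -(n[0] * w0[0] + n[1] * w0[1] + n[2] * w0[2]) / denom;
  if (t <= 1e-10 || t >= 1 - 1e-10) return false;
  double x[3];
  for (int i = 0; i < 3; ++i) x[i] = p[i] + t * dir[i] - a[i];
  double uu = u[0] * u[0] + u[1] * u[1] + u[2] * u[2];
  double uv = u[0] * vv[0] + u[1] * vv[1] + u[2] * vv[2];
  double vvv = vv[0] * vv[0] + vv[1] * vv[1] + vv[2] * vv[2];
  double xu = x[0] * u[0] + x[1] * u[1] + x[2] * u[2];
  double xv = x[0] * vv[0] + x[1] * vv[1] + x[2] * vv[2];
  double det = uu * vvv - uv * uv;
  if (std::fabs(det) < 1e-20) return false;
  double s = (vvv * xu - uv * xv) / det;
  double tt = (uu * xv - uv * xu) / det;
  return s > 1e-10 && tt > 1e-10 && s + tt < 1 - 1e-10;
}

static bool tri_tri_intersect(const double *a0, const double *a1,
                              const double *a2, const double *b0,
                              const double *b1, const double *b2) {
  return seg_tri_intersect(a0, a1, b0, b1, b2) ||
         seg_tri_intersect(a1, a2, b0, b1, b2) ||
         seg_tri_intersect(a2, a0, b0, b1, b2) ||
         seg_tri_intersect(b0, b1, a0, a1, a2) ||
         seg_tri_intersect(b1, b2, a0, a1, a2) ||
         seg_tri_intersect(b2, b0, a0, a1, a2);
}

// [[Rcpp::export]]
IntegerMatrix cpp_self_intersection_pairs(NumericMatrix V, IntegerMatrix F) {
  int nf = F.nrow();
  std::vector<int> hits;
  if (nf == 0) return IntegerMatrix(0, 2);
  // cell size from mean triangle bbox diagonal
  double minb[3] = {R_PosInf, R_PosInf, R_PosInf};
  double maxb[3] = {R_NegInf, R_NegInf, R_NegInf};
  std::vector<double> tmin(3 * nf), tmax(3 * nf);
  double meansz = 0;
  for (int f = 0; f < nf; ++f) {
    for (int d = 0; d < 3; ++d) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int k = 0; k < 3; ++k) {
        double x = V(F(f, k) - 1, d);
        lo = std::min(lo, x);
        hi = std::max(hi, x);
      }
      tmin[3 * f + d] = lo;
      tmax[3 * f + d] = hi;
      minb[d] = std::min(minb[d], lo);
      maxb[d] = std::max(maxb[d], hi);
      meansz += (hi - lo);
    }
  }
  double cell = std::max(1e-9, meansz / (3.0 * nf) * 2.0);
  auto cellIdx = [&](double x, int d) {
    return (long long)std::floor((x - minb[d]) / cell);
  };
  std::unordered_map<long long, std::vector<int>> grid;
  long long H1 = 73856093LL, H2 = 19349663LL, H3 = 83492791LL;
  for (int f = 0; f < nf; ++f) {
    long long i0 = cellIdx(tmin[3 * f], 0), i1 = cellIdx(tmax[3 * f], 0);
    long long j0 = cellIdx(tmin[3 * f + 1], 1), j1 = cellIdx(tmax[3 * f + 1], 1);
    long long k0 = cellIdx(tmin[3 * f + 2], 2), k1 = cellIdx(tmax[3 * f + 2], 2);
    for (long long i = i0; i <= i1; ++i)
      for (long long j = j0; j <= j1; ++j)
        for (long long k = k0; k <= k1; ++k)
          grid[i * H1 ^ j * H2 ^ k * H3].push_back(f);
  }
  int count = 0;
  std::unordered_set<long long> done;
  for (auto &kv : grid) {
    auto &cellv = kv.second;
    for (size_t x = 0; x < cellv.size(); ++x)
      for (size_t y = x + 1; y < cellv.size(); ++y) {
        int f = std::min(cellv[x], cellv[y]);
        int g = std::max(cellv[x], cellv[y]);
        long long pk = (long long)f * nf + g;
        if (done.count(pk)) continue;
        done.insert(pk);
        // skip pairs sharing a vertex
        bool share = false;
        for (int a = 0; a < 3 && !share; ++a)
          for (int b = 0; b < 3; ++b)
            if (F(f, a) == F(g, b)) {
              share = true;
              break;
            }
        if (share) continue;
        // bbox overlap
        bool overlap = true;
        for (int d = 0; d < 3; ++d)
          if (tmin[3 * f + d] > tmax[3 * g + d] ||
              tmin[3 * g + d] > tmax[3 * f + d]) {
            overlap = false;
            break;
          }
        if (!overlap) continue;
        double A0[3], A1[3], A2[3], B0[3], B1[3], B2[3];
        for (int d = 0; d < 3; ++d) {
          A0[d] = V(F(f, 0) - 1, d);
          A1[d] = V(F(f, 1) - 1, d);
          A2[d] = V(F(f, 2) - 1, d);
          B0[d] = V(F(g, 0) - 1, d);
          B1[d] = V(F(g, 1) - 1, d);
          B2[d] = V(F(g, 2) - 1, d);
        }
        if (tri_tri_intersect(A0, A1, A2, B0, B1, B2)) {
          ++count;
          hits.push_back(f + 1);
          hits.push_back(g + 1);
        }
      }
  }
  IntegerMatrix out(count, 2);
  for (int i = 0; i < count; ++i) {
    out(i, 0) = hits[2 * i];
    out(i, 1) = hits[2 * i + 1];
  }
  return out;
}

// [[Rcpp::export]]
int cpp_self_intersections(NumericMatrix V, IntegerMatrix F) {
  return cpp_self_intersection_pairs(V, F).nrow();
}

// distance from each vertex to the nearest *facing* vertex (normals with
// negative dot product) not in its exclusion list (CSR arrays xp/xi,
// 0-based), capped at `cutoff`; used to detect approaching sheets of the
// same surface
// [[Rcpp::export]]
NumericVector cpp_nonlocal_min_dist(NumericMatrix V, NumericMatrix N,
                                    IntegerVector xp, IntegerVector xi,
                                    double cutoff) {
  int n = V.nrow();
  NumericVector out(n, cutoff);
  double minb[3];
  for (int d = 0; d < 3; ++d) {
    double lo = R_PosInf;
    for (int i = 0; i < n; ++i) lo = std::min(lo, V(i, d));
    minb[d] = lo;
  }
  double cell = cutoff;
  std::unordered_map<long long, std::vector<int>> grid;
  long long H1 = 73856093LL, H2 = 19349663LL, H3 = 83492791LL;
  auto keyOf = [&](double x, double y, double z) {
    long long i = (long long)std::floor((x - minb[0]) / cell);
    long long j = (long long)std::floor((y - minb[1]) / cell);
    long long k = (long long)std::floor((z - minb[2]) / cell);
    return std::make_tuple(i, j, k);
  };
  for (int i = 0; i < n; ++i) {
    auto t = keyOf(V(i, 0), V(i, 1), V(i, 2));
    grid[std::get<0>(t) * H1 ^ std::get<1>(t) * H2 ^ std::get<2>(t) * H3]
        .push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    std::unordered_set<int> excl;
    for (int p = xp[i]; p < xp[i + 1]; ++p) excl.insert(xi[p]);
    excl.insert(i);
    auto t = keyOf(V(i, 0), V(i, 1), V(i, 2));
    long long ci = std::get<0>(t), cj = std::get<1>(t), ck = std::get<2>(t);
    double best = cutoff;
    for (long long a = ci - 1; a <= ci + 1; ++a)
      for (long long b = cj - 1; b <= cj + 1; ++b)
        for (long long c = ck - 1; c <= ck + 1; ++c) {
          auto it = grid.find(a * H1 ^ b * H2 ^ c * H3);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (excl.count(j)) continue;
            if (N(i, 0) * N(j, 0) + N(i, 1) * N(j, 1) + N(i, 2) * N(j, 2) >= 0)
              continue; // same-facing: not an approaching sheet
            double dx = V(i, 0) - V(j, 0), dy = V(i, 1) - V(j, 1),
                   dz = V(i, 2) - V(j, 2);
            double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            if (d < best) best = d;
          }
        }
    out[i] = best;
  }
  return out;
}
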