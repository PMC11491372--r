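#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Arrays are 3-D, column-major, dim = (nz, ny, nx): index = z + nz*(y + ny*x).

static inline int reflect(int i, int n) {
  // reflect-101 boundary: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + r] = v;
    s += v;
  }
  for (double& v : k) v /= s;
  return k;
}

static void conv_axis(std::vector<double>& a, int nz, int ny, int nx,
                      const std::vector<double>& k, int axis) {
  int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  std::vector<double> out(a.size());
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          int zz = z, yy = y, xx = x;
          if (axis == 0) zz = reflect(z + t, nz);
          else if (axis == 1) yy = reflect(y + t, ny);
          else xx = reflect(x + t, nx);
          acc += k[t + r] * a[zz + (size_t)nz * (yy + (size_t)ny * xx)];
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = acc;
      }
    }
  }
  a.swap(out);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector arr, IntegerVector dim,
                          double sz, double sy, double sx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(arr.begin(), arr.end());
  conv_axis(a, nz, ny, nx, gauss_kernel(sz), 0);
  conv_axis(a, nz, ny, nx, gauss_kernel(sy), 1);
  conv_axis(a, nz, ny, nx, gauss_kernel(sx), 2);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling, connectivity 6 or 26, labels 1..K by
// discovery order (scan order: z fastest).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int z = cur % nz, y = (cur / nz) % ny, x = cur / ((size_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dz = -1; dz <= 1; ++dz) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            if (connectivity == 6 && std::abs(dz) + std::abs(dy) + std::abs(dx) != 1)
              continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Fill cavities: background voxels not 6-connected to the array border
// become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes3d(LogicalVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<uint8_t> outside(n, 0);
  std::vector<size_t> stack;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 && x != 0 && x != nx - 1)
          continue;
        size_t i = z + (size_t)nz * (y + (size_t)ny * x);
        if (!mask[i] && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
    }
  }
  const int dz6[6] = {1, -1, 0, 0, 0, 0};
  const int dy6[6] = {0, 0, 1, -1, 0, 0};
  const int dx6[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    size_t cur = stack.back();
    stack.pop_back();
    int z = cur % nz, y = (cur / nz) % ny, x = cur / ((size_t)nz * ny);
    for (int k = 0; k < 6; ++k) {
      int zz = z + dz6[k], yy = y + dy6[k], xx = x + dx6[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      size_t j = zz + (size_t)nz * (yy + (size_t)ny * xx);
      if (!mask[j] && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

static void minmax_axis(std::vector<uint8_t>& a, int nz, int ny, int nx,
                        int r, int axis, bool take_max) {
  if (r <= 0) return;
  std::vector<uint8_t> out(a.size());
  int n_axis = axis == 0 ? nz : (axis == 1 ? ny : nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int c = axis == 0 ? z : (axis == 1 ? y : x);
        uint8_t acc = take_max ? 0 : 1;
        for (int t = std::max(0, c - r); t <= std::min(n_axis - 1, c + r); ++t) {
          int zz = axis == 0 ? t : z, yy = axis == 1 ? t : y, xx = axis == 2 ? t : x;
          uint8_t v = a[zz + (size_t)nz * (yy + (size_t)ny * xx)];
          if (take_max) { if (v) { acc = 1; break; } }
          else { if (!v) { acc = 0; break; } }
        }
        out[z + (size_t)nz * (y + (size_t)ny * x)] = acc;
      }
    }
  }
  a.swap(out);
}

// Box dilation/erosion with per-axis radii (separable; structuring element is
// a box, adequate for closing at the scale used here).
// [[Rcpp::export]]
LogicalVector cpp_morph3d(LogicalVector mask, IntegerVector dim,
                          IntegerVector radius, bool dilate) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  std::vector<uint8_t> a(n);
  for (size_t i = 0; i < n; ++i) a[i] = mask[i] ? 1 : 0;
  minmax_axis(a, nz, ny, nx, radius[0], 0, dilate);
  minmax_axis(a, nz, ny, nx, radius[1], 1, dilate);
  minmax_axis(a, nz, ny, nx, radius[2], 2, dilate);
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = a[i] != 0;
  out.attr("dim") = dim;
  return out;
}
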