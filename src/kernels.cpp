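#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling of a binary mask.
// 2D: 8-connectivity. 3D: 26-connectivity. Labels are assigned in raster-scan
// order of the first voxel of each component, so output is deterministic.
// [[Rcpp::export(name = ".cc_label")]]
IntegerVector cc_label(LogicalVector mask, IntegerVector dim) {
  int nd = dim.size();
  int nx = dim[0], ny = dim[1], nz = (nd == 3) ? dim[2] : 1;
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back(); stack.pop_back();
      int x = cur % nx, y = (cur / nx) % ny, z = cur / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            size_t t = (size_t)xx + (size_t)nx * (yy + (size_t)ny * zz);
            if (mask[t] && !lab[t]) { lab[t] = next; stack.push_back(t); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

static void conv1d_axis(std::vector<double> &a, int nx, int ny, int nz,
                        const std::vector<double> &w, int axis) {
  int h = ((int)w.size() - 1) / 2;
  std::vector<double> line;
  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  line.resize(len);
  size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)nx : (size_t)nx * ny;
  int n_outer1 = (axis == 0) ? ny : nx;
  int n_outer2 = (axis == 2) ? ny : nz;
  for (int o2 = 0; o2 < n_outer2; ++o2) {
    for (int o1 = 0; o1 < n_outer1; ++o1) {
      size_t base;
      if (axis == 0)      base = (size_t)nx * (o1 + (size_t)ny * o2);
      else if (axis == 1) base = (size_t)o1 + (size_t)nx * ny * o2;
      else                base = (size_t)o1 + (size_t)nx * o2;
      for (int i = 0; i < len; ++i) line[i] = a[base + stride * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int k = -h; k <= h; ++k) {
          int j = i + k;
          if (j < 0 || j >= len) continue;  // zero padding
          acc += line[j] * w[k + h];
        }
        a[base + stride * i] = acc;
      }
    }
  }
}

// Separable Gaussian blur with per-axis sigma (in voxel units); zero-padded
// borders. Works for 2D (dim length 2) and 3D arrays.
// [[Rcpp::export(name = ".gauss_blur")]]
NumericVector gauss_blur(NumericVector x, IntegerVector dim, NumericVector sigma) {
  int nd = dim.size();
  int nx = dim[0], ny = dim[1], nz = (nd == 3) ? dim[2] : 1;
  std::vector<double> a(x.begin(), x.end());
  for (int axis = 0; axis < nd; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int h = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * h + 1);
    double tot = 0.0;
    for (int k = -h; k <= h; ++k) { w[k + h] = std::exp(-0.5 * k * k / (s * s)); tot += w[k + h]; }
    for (double &v : w) v /= tot;
    conv1d_axis(a, nx, ny, nz, w, axis);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

static inline void interp_pt(const double *p1, const double *p2, double v1,
                             double v2, double iso, double *out) {
  double t = (iso - v1) / (v2 - v1);
  for (int k = 0; k < 3; ++k) out[k] = p1[k] + t * (p2[k] - p1[k]);
}

static inline double tri_area(const double *a, const double *b, const double *c) {
  double u[3], v[3];
  for (int k = 0; k < 3; ++k) { u[k] = b[k] - a[k]; v[k] = c[k] - a[k]; }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Iso-surface area at level `iso` by marching tetrahedra (6 tetrahedra per
// grid cell, linear interpolation along edges), in physical units given the
// per-axis voxel spacing.
// [[Rcpp::export(name = ".mt_surface_area")]]
double mt_surface_area(NumericVector field, IntegerVector dim,
                       NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *F = REAL(field);
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };
  double area = 0.0;
  double corner[8][3], val[8], p[4][3];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dz = (c >> 2) & 1;
          corner[c][0] = (x + dx) * spacing[0];
          corner[c][1] = (y + dy) * spacing[1];
          corner[c][2] = (z + dz) * spacing[2];
          val[c] = F[(size_t)(x + dx) + (size_t)nx * ((y + dy) + (size_t)ny * (z + dz))];
          (val[c] >= iso) ? any_in = true : any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int inmask = 0, nin = 0;
          for (int k = 0; k < 4; ++k)
            if (val[T[k]] >= iso) { inmask |= (1 << k); ++nin; }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            int lone = -1;
            for (int k = 0; k < 4; ++k) {
              bool in = (inmask >> k) & 1;
              if ((nin == 1 && in) || (nin == 3 && !in)) lone = k;
            }
            int j = 0;
            for (int k = 0; k < 4; ++k)
              if (k != lone)
                interp_pt(corner[T[lone]], corner[T[k]], val[T[lone]], val[T[k]], iso, p[j++]);
            area += tri_area(p[0], p[1], p[2]);
          } else {
            int in_[2], out_[2], ai = 0, bi = 0;
            for (int k = 0; k < 4; ++k)
              ((inmask >> k) & 1) ? (in_[ai++] = k) : (out_[bi++] = k);
            interp_pt(corner[T[in_[0]]], corner[T[out_[0]]], val[T[in_[0]]], val[T[out_[0]]], iso, p[0]);
            interp_pt(corner[T[in_[0]]], corner[T[out_[1]]], val[T[in_[0]]], val[T[out_[1]]], iso, p[1]);
            interp_pt(corner[T[in_[1]]], corner[T[out_[1]]], val[T[in_[1]]], val[T[out_[1]]], iso, p[2]);
            interp_pt(corner[T[in_[1]]], corner[T[out_[0]]], val[T[in_[1]]], val[T[out_[0]]], iso, p[3]);
            area += tri_area(p[0], p[1], p[2]) + tri_area(p[0], p[2], p[3]);
          }
        }
      }
  return area;
}
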