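// 3D volume operations for the segmentation stage: level-set curvature flow
// denoising, separable Gaussian smoothing, 26-connected local maxima, and
// seeded priority-flood region growth. Volumes are arrays with dim
// (nz, ny, nx); operations run in index space unless stated otherwise.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
NumericVector curvature_flow_cpp(NumericVector vol, IntegerVector dim,
                                 int iterations, double timestep) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  auto IDX = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x);
  };
  const double eps = 1e-12;
  for (int it = 0; it < iterations; ++it) {
    for (int x = 0; x < nx; ++x) {
      int xm = clampi(x - 1, 0, nx - 1), xp = clampi(x + 1, 0, nx - 1);
      for (int y = 0; y < ny; ++y) {
        int ym = clampi(y - 1, 0, ny - 1), yp = clampi(y + 1, 0, ny - 1);
        for (int z = 0; z < nz; ++z) {
          int zm = clampi(z - 1, 0, nz - 1), zp = clampi(z + 1, 0, nz - 1);
          double c = a[IDX(z, y, x)];
          double vxp = a[IDX(z, y, xp)], vxm = a[IDX(z, y, xm)];
          double vyp = a[IDX(z, yp, x)], vym = a[IDX(z, ym, x)];
          double vzp = a[IDX(zp, y, x)], vzm = a[IDX(zm, y, x)];
          double Ix = 0.5 * (vxp - vxm), Iy = 0.5 * (vyp - vym),
                 Iz = 0.5 * (vzp - vzm);
          double Ixx = vxp - 2 * c + vxm, Iyy = vyp - 2 * c + vym,
                 Izz = vzp - 2 * c + vzm;
          double Ixy = 0.25 * (a[IDX(z, yp, xp)] - a[IDX(z, yp, xm)] -
                               a[IDX(z, ym, xp)] + a[IDX(z, ym, xm)]);
          double Ixz = 0.25 * (a[IDX(zp, y, xp)] - a[IDX(zp, y, xm)] -
                               a[IDX(zm, y, xp)] + a[IDX(zm, y, xm)]);
          double Iyz = 0.25 * (a[IDX(zp, yp, x)] - a[IDX(zp, ym, x)] -
                               a[IDX(zm, yp, x)] + a[IDX(zm, ym, x)]);
          double g2 = Ix * Ix + Iy * Iy + Iz * Iz;
          double num = Ixx * (Iy * Iy + Iz * Iz) +
                       Iyy * (Ix * Ix + Iz * Iz) +
                       Izz * (Ix * Ix + Iy * Iy) -
                       2 * (Ix * Iy * Ixy + Ix * Iz * Ixz + Iy * Iz * Iyz);
          b[IDX(z, y, x)] = c + timestep * num / (g2 + eps);
        }
      }
    }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

static void blur_axis(std::vector<double> &a, int n0, int n1, int n2,
                      double sigma, int axis) {
  // blur along `axis` of an array with dims (n0, n1, n2), col-major
  if (sigma <= 0) return;
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * radius + 1);
  double s = 0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &v : k) v /= s;
  int dims[3] = {n0, n1, n2};
  size_t stride[3] = {1, (size_t)n0, (size_t)n0 * n1};
  int nA = dims[axis];
  size_t sA = stride[axis];
  int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
  std::vector<double> line(nA);
  for (int i1 = 0; i1 < dims[o1]; ++i1) {
    for (int i2 = 0; i2 < dims[o2]; ++i2) {
      size_t base = stride[o1] * i1 + stride[o2] * i2;
      for (int i = 0; i < nA; ++i) {
        double acc = 0;
        for (int j = -radius; j <= radius; ++j) {
          int idx = i + j;
          if (idx < 0) idx = -idx;                    // reflect
          if (idx >= nA) idx = 2 * nA - 2 - idx;
          idx = clampi(idx, 0, nA - 1);
          acc += k[j + radius] * a[base + sA * idx];
        }
        line[i] = acc;
      }
      for (int i = 0; i < nA; ++i) a[base + sA * i] = line[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector sigma_vox) {
  // sigma_vox in (z, y, x) order to match dim
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  blur_axis(a, nz, ny, nx, sigma_vox[0], 0);
  blur_axis(a, nz, ny, nx, sigma_vox[1], 1);
  blur_axis(a, nz, ny, nx, sigma_vox[2], 2);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector laplacian_cpp(NumericVector vol, IntegerVector dim,
                            NumericVector spacing_zyx) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double *a = vol.begin();
  NumericVector out(vol.size());
  out.attr("dim") = dim;
  double wz = 1.0 / (spacing_zyx[0] * spacing_zyx[0]);
  double wy = 1.0 / (spacing_zyx[1] * spacing_zyx[1]);
  double wx = 1.0 / (spacing_zyx[2] * spacing_zyx[2]);
  auto IDX = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x);
  };
  for (int x = 0; x < nx; ++x) {
    int xm = clampi(x - 1, 0, nx - 1), xp = clampi(x + 1, 0, nx - 1);
    for (int y = 0; y < ny; ++y) {
      int ym = clampi(y - 1, 0, ny - 1), yp = clampi(y + 1, 0, ny - 1);
      for (int z = 0; z < nz; ++z) {
        int zm = clampi(z - 1, 0, nz - 1), zp = clampi(z + 1, 0, nz - 1);
        double c = a[IDX(z, y, x)];
        out[IDX(z, y, x)] =
            wx * (a[IDX(z, y, xp)] - 2 * c + a[IDX(z, y, xm)]) +
            wy * (a[IDX(z, yp, x)] - 2 * c + a[IDX(z, ym, x)]) +
            wz * (a[IDX(zp, y, x)] - 2 * c + a[IDX(zm, y, x)]);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(NumericVector vol, IntegerVector dim,
                               double threshold) {
  // strict 26-neighbourhood maxima (ties broken towards the earlier index)
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double *a = vol.begin();
  auto IDX = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x);
  };
  std::vector<std::array<int, 3>> hits;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        size_t ci = IDX(z, y, x);
        double c = a[ci];
        if (c < threshold) continue;
        bool ok = true;
        for (int dx = -1; dx <= 1 && ok; ++dx)
          for (int dy = -1; dy <= 1 && ok; ++dy)
            for (int dz = -1; dz <= 1 && ok; ++dz) {
              if (!dx && !dy && !dz) continue;
              int X = x + dx, Y = y + dy, Z = z + dz;
              if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
                continue;
              size_t ni = IDX(Z, Y, X);
              if (a[ni] > c || (a[ni] == c && ni < ci)) ok = false;
            }
        if (ok) hits.push_back({z, y, x});
      }
  IntegerMatrix out((int)hits.size(), 3);
  for (size_t i = 0; i < hits.size(); ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = hits[i][k] + 1;  // 1-based z,y,x
  return out;
}

// [[Rcpp::export]]
IntegerVector grow_labels_cpp(NumericVector vol, IntegerVector dim,
                              IntegerMatrix seeds, double threshold) {
  // watershed-style growth: flood from seeds in order of decreasing
  // intensity, restricted to voxels >= threshold, 26-connectivity
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double *a = vol.begin();
  auto IDX = [&](int z, int y, int x) {
    return (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x);
  };
  IntegerVector labels(vol.size(), 0);
  labels.attr("dim") = dim;
  typedef std::pair<double, std::pair<size_t, int>> QE;  // (val, (voxel, lab))
  std::priority_queue<QE> pq;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int z = seeds(s, 0) - 1, y = seeds(s, 1) - 1, x = seeds(s, 2) - 1;
    size_t i = IDX(z, y, x);
    pq.push({a[i], {i, s + 1}});
  }
  while (!pq.empty()) {
    QE e = pq.top();
    pq.pop();
    size_t i = e.second.first;
    int lab = e.second.second;
    if (labels[i] != 0) continue;
    labels[i] = lab;
    int x = (int)(i / ((size_t)nz * ny));
    int y = (int)((i / nz) % ny);
    int z = (int)(i % nz);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          int X = x + dx, Y = y + dy, Z = z + dz;
          if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz)
            continue;
          size_t ni = IDX(Z, Y, X);
          if (labels[ni] == 0 && a[ni] >= threshold)
            pq.push({a[ni], {ni, lab}});
        }
  }
  return labels;
}
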