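// Low-level 3D voxel operations backing the nuclear segmentation:
// per-slice box means (adaptive threshold), separable Gaussian blur,
// 3D connected-component labelling, minima-seeded watershed regions,
// binary erosion/dilation, and exposed-face surface areas.
// Arrays are column-major (x fastest), 0-based internally.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-neighbourhood offsets
static void neighbours26(std::vector<int>& dx, std::vector<int>& dy, std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

static const int DX6[6] = { 1, -1, 0, 0, 0, 0 };
static const int DY6[6] = { 0, 0, 1, -1, 0, 0 };
static const int DZ6[6] = { 0, 0, 0, 0, 1, -1 };

// Local mean over a w x w window (clipped at borders) in each XY slice.
// [[Rcpp::export]]
NumericVector cpp_box_mean_xy(NumericVector arr, int nx, int ny, int nz, int w) {
  int r = w / 2;
  NumericVector out(arr.size());
  std::vector<double> integ((size_t)(nx + 1) * (ny + 1));
  for (int z = 0; z < nz; ++z) {
    // integral image with one-row/col zero padding
    for (int y = 0; y <= ny; ++y) integ[(size_t)0 + (size_t)(nx + 1) * y] = 0.0;
    for (int x = 0; x <= nx; ++x) integ[(size_t)x] = 0.0;
    for (int y = 1; y <= ny; ++y) {
      double rowsum = 0.0;
      for (int x = 1; x <= nx; ++x) {
        rowsum += arr[vidx(x - 1, y - 1, z, nx, ny)];
        integ[(size_t)x + (size_t)(nx + 1) * y] =
          integ[(size_t)x + (size_t)(nx + 1) * (y - 1)] + rowsum;
      }
    }
    for (int y = 0; y < ny; ++y) {
      int y0 = std::max(0, y - r), y1 = std::min(ny - 1, y + r);
      for (int x = 0; x < nx; ++x) {
        int x0 = std::max(0, x - r), x1 = std::min(nx - 1, x + r);
        double s = integ[(size_t)(x1 + 1) + (size_t)(nx + 1) * (y1 + 1)]
                 - integ[(size_t)x0       + (size_t)(nx + 1) * (y1 + 1)]
                 - integ[(size_t)(x1 + 1) + (size_t)(nx + 1) * y0]
                 + integ[(size_t)x0       + (size_t)(nx + 1) * y0];
        int n = (x1 - x0 + 1) * (y1 - y0 + 1);
        out[vidx(x, y, z, nx, ny)] = s / n;
      }
    }
  }
  return out;
}

static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      double sigma, int axis) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  int len = (axis == 0) ? nx : (axis == 1 ? ny : nz);
  std::vector<double> line(len), res(len);
  int n_outer1 = (axis == 0) ? ny : nx;
  int n_outer2 = (axis == 2) ? ny : nz;
  for (int o2 = 0; o2 < n_outer2; ++o2) {
    for (int o1 = 0; o1 < n_outer1; ++o1) {
      for (int i = 0; i < len; ++i) {
        int x = (axis == 0) ? i : o1;
        int y = (axis == 1) ? i : (axis == 0 ? o1 : o2);
        int z = (axis == 2) ? i : o2;
        line[i] = a[vidx(x, y, z, nx, ny)];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p < 0) p = -p - 1;            // reflect
          if (p >= len) p = 2 * len - p - 1;
          if (p < 0) p = 0;
          if (p >= len) p = len - 1;        // guard tiny axes
          acc += k[j + r] * line[p];
        }
        res[i] = acc;
      }
      for (int i = 0; i < len; ++i) {
        int x = (axis == 0) ? i : o1;
        int y = (axis == 1) ? i : (axis == 0 ? o1 : o2);
        int z = (axis == 2) ? i : o2;
        a[vidx(x, y, z, nx, ny)] = res[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur_3d(NumericVector arr, int nx, int ny, int nz,
                                   double sx, double sy, double sz) {
  std::vector<double> a(arr.begin(), arr.end());
  blur_axis(a, nx, ny, nz, sx, 0);
  blur_axis(a, nx, ny, nz, sy, 1);
  blur_axis(a, nx, ny, nz, sz, 2);
  return NumericVector(a.begin(), a.end());
}

// Connected components of a binary mask; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int nx, int ny, int nz,
                                   int connectivity) {
  std::vector<int> dx, dy, dz;
  if (connectivity == 26) {
    neighbours26(dx, dy, dz);
  } else {
    for (int i = 0; i < 6; ++i) { dx.push_back(DX6[i]); dy.push_back(DY6[i]); dz.push_back(DZ6[i]); }
  }
  int nn = dx.size();
  IntegerVector labels(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(x, y, z, nx, ny);
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
          for (int k = 0; k < nn; ++k) {
            int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
            int p = vidx(px, py, pz, nx, ny);
            if (mask[p] && labels[p] == 0) { labels[p] = next; stack.push_back(p); }
          }
        }
      }
  return labels;
}

// Watershed regions of a topographic surface: label regional minima
// (plateau-aware, 26-connected), then priority-flood the whole volume.
// Every voxel receives a region label >= 1.
// [[Rcpp::export]]
IntegerVector cpp_watershed_regions(NumericVector surface, int nx, int ny, int nz) {
  std::vector<int> dx, dy, dz;
  neighbours26(dx, dy, dz);
  int nn = dx.size();
  R_xlen_t n = surface.size();
  IntegerVector labels(n, 0);
  std::vector<char> visited(n, 0);
  int next = 0;
  std::vector<int> plateau, stack;

  // regional minima detection
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(x, y, z, nx, ny);
        if (visited[i]) continue;
        double v = surface[i];
        bool is_min = true;
        plateau.clear(); stack.clear();
        stack.push_back(i);
        visited[i] = 1;
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          plateau.push_back(cur);
          int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
          for (int k = 0; k < nn; ++k) {
            int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
            int p = vidx(px, py, pz, nx, ny);
            if (surface[p] < v) { is_min = false; continue; }
            if (surface[p] == v && !visited[p]) { visited[p] = 1; stack.push_back(p); }
          }
        }
        if (is_min) {
          ++next;
          for (int p : plateau) labels[p] = next;
        }
      }

  // priority flood from the minima
  typedef std::pair<double, std::pair<long long, int> > QE; // (value, (order, idx))
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  std::vector<char> queued(n, 0);
  long long order = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] > 0) { pq.push(QE(surface[i], std::make_pair(order++, (int)i))); queued[i] = 1; }
  while (!pq.empty()) {
    int cur = pq.top().second.second; pq.pop();
    int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
    for (int k = 0; k < nn; ++k) {
      int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
      if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
      int p = vidx(px, py, pz, nx, ny);
      if (labels[p] == 0 && !queued[p]) {
        labels[p] = labels[cur];
        queued[p] = 1;
        pq.push(QE(surface[p], std::make_pair(order++, p)));
      }
    }
  }
  return labels;
}

// TRUE where a voxel has a 26-neighbour carrying a different positive label
// (26-neighbourhood so the removed boundary also blocks diagonal paths
// under 26-connected labelling).
// [[Rcpp::export]]
LogicalVector cpp_region_boundary(IntegerVector labels, int nx, int ny, int nz) {
  std::vector<int> dx, dy, dz;
  neighbours26(dx, dy, dz);
  int nn = dx.size();
  LogicalVector out(labels.size(), false);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(x, y, z, nx, ny);
        int li = labels[i];
        if (li <= 0) continue;
        for (int k = 0; k < nn; ++k) {
          int px = x + dx[k], py = y + dy[k], pz = z + dz[k];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
          int lp = labels[vidx(px, py, pz, nx, ny)];
          if (lp > 0 && lp != li) { out[i] = true; break; }
        }
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_binary_erode6(LogicalVector mask, int nx, int ny, int nz) {
  LogicalVector out(mask.size(), false);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(x, y, z, nx, ny);
        if (!mask[i]) continue;
        bool keep = true;
        for (int k = 0; k < 6; ++k) {
          int px = x + DX6[k], py = y + DY6[k], pz = z + DZ6[k];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) { keep = false; break; }
          if (!mask[vidx(px, py, pz, nx, ny)]) { keep = false; break; }
        }
        out[i] = keep;
      }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_binary_dilate6(LogicalVector mask, int nx, int ny, int nz) {
  LogicalVector out(mask.size(), false);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(x, y, z, nx, ny);
        if (mask[i]) { out[i] = true; continue; }
        for (int k = 0; k < 6; ++k) {
          int px = x + DX6[k], py = y + DY6[k], pz = z + DZ6[k];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) continue;
          if (mask[vidx(px, py, pz, nx, ny)]) { out[i] = true; break; }
        }
      }
  return out;
}

// Exposed voxel faces per label: faces adjoining a different label,
// background, or the array boundary.
// [[Rcpp::export]]
IntegerVector cpp_surface_counts(IntegerVector labels, int nx, int ny, int nz,
                                 int nlabels) {
  IntegerVector out(nlabels, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = vidx(x, y, z, nx, ny);
        int li = labels[i];
        if (li <= 0 || li > nlabels) continue;
        for (int k = 0; k < 6; ++k) {
          int px = x + DX6[k], py = y + DY6[k], pz = z + DZ6[k];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz) {
            out[li - 1]++;
            continue;
          }
          if (labels[vidx(px, py, pz, nx, ny)] != li) out[li - 1]++;
        }
      }
  return out;
}
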