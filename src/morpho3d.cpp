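// Low-level 3D morphology kernels shared by the segmentation and
// morphometry layers. Arrays arrive as flat vectors in R array order
// (first index fastest): linear index = z + nz*(y + ny*x) for dims
// (nz, ny, nx).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Dims {
  int nz, ny, nx;
  long n() const { return (long)nz * ny * nx; }
  long idx(int z, int y, int x) const { return (long)z + (long)nz * (y + (long)ny * x); }
};

Dims as_dims(const IntegerVector &d) {
  if (d.size() != 3) stop("expected 3D dims");
  Dims dd; dd.nz = d[0]; dd.ny = d[1]; dd.nx = d[2];
  return dd;
}

// neighbor offsets for 6- or 26-connectivity
std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int l1 = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && l1 != 1) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

}  // namespace

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");
  Dims d = as_dims(dims);
  if ((long)mask.size() != d.n()) stop("mask length does not match dims");
  IntegerVector labels(mask.size(), 0);
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  std::vector<long> stack;
  int next = 0;
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z) {
        long i = d.idx(z, y, x);
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          long cur = stack.back();
          stack.pop_back();
          int cz = (int)(cur % d.nz);
          long rest = cur / d.nz;
          int cy = (int)(rest % d.ny);
          int cx = (int)(rest / d.ny);
          for (const auto &o : off) {
            int nz2 = cz + o[0], ny2 = cy + o[1], nx2 = cx + o[2];
            if (nz2 < 0 || ny2 < 0 || nx2 < 0 || nz2 >= d.nz || ny2 >= d.ny || nx2 >= d.nx)
              continue;
            long j = d.idx(nz2, ny2, nx2);
            if (mask[j] && labels[j] == 0) {
              labels[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
  return labels;
}

// Background voxels (mask == FALSE) reachable from the array border by a
// 6-connected flood. Complement of foreground uses 6-connectivity so that
// 26-connected foreground shells enclose their cavities.
// [[Rcpp::export(name = ".cc_border_reach3d")]]
LogicalVector cc_border_reach3d(LogicalVector mask, IntegerVector dims) {
  Dims d = as_dims(dims);
  if ((long)mask.size() != d.n()) stop("mask length does not match dims");
  LogicalVector reached(mask.size(), FALSE);
  std::vector<std::array<int, 3>> off = neighbor_offsets(6);
  std::vector<long> stack;
  auto push_if = [&](int z, int y, int x) {
    long i = d.idx(z, y, x);
    if (!mask[i] && !reached[i]) {
      reached[i] = TRUE;
      stack.push_back(i);
    }
  };
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y)
      for (int z = 0; z < d.nz; ++z)
        if (z == 0 || y == 0 || x == 0 || z == d.nz - 1 || y == d.ny - 1 || x == d.nx - 1)
          push_if(z, y, x);
  while (!stack.empty()) {
    long cur = stack.back();
    stack.pop_back();
    int cz = (int)(cur % d.nz);
    long rest = cur / d.nz;
    int cy = (int)(rest % d.ny);
    int cx = (int)(rest / d.ny);
    for (const auto &o : off) {
      int nz2 = cz + o[0], ny2 = cy + o[1], nx2 = cx + o[2];
      if (nz2 < 0 || ny2 < 0 || nx2 < 0 || nz2 >= d.nz || ny2 >= d.ny || nx2 >= d.nx)
        continue;
      push_if(nz2, ny2, nx2);
    }
  }
  return reached;
}

namespace {
// Felzenszwalb & Huttenlocher 1D squared distance transform with grid
// spacing s (sample positions i*s).
void dt1d(std::vector<double> &f, int n, double s, std::vector<double> &dst,
          std::vector<int> &v, std::vector<double> &zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -INFINITY;
  zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * s;
    double sden, sp;
    for (;;) {
      double vv = (double)v[k] * s;
      sden = 2.0 * (qq - vv);
      sp = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / sden;
      if (sp <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = sp;
    zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * s;
    while (zb[k + 1] < qq) ++k;
    double vv = (double)v[k] * s;
    dst[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}
}  // namespace

// Squared Euclidean distance (um^2) from each foreground voxel to the
// nearest background voxel, with anisotropic spacing (dz, dy, dx).
// Voxels outside the array are treated as background.
// [[Rcpp::export(name = ".edt_sq3d")]]
NumericVector edt_sq3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  Dims d = as_dims(dims);
  if ((long)mask.size() != d.n()) stop("mask length does not match dims");
  if (spacing.size() != 3) stop("spacing must have length 3");
  const double BIG = 1e30;
  NumericVector out(mask.size());
  for (long i = 0; i < (long)mask.size(); ++i) out[i] = mask[i] ? BIG : 0.0;
  int nmax = std::max(d.nz, std::max(d.ny, d.nx));
  std::vector<double> f(nmax), dst(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);

  // pad with background at +/- one voxel beyond each face: handled by
  // clamping the line transform result against distance to the face.
  // pass along z
  for (int x = 0; x < d.nx; ++x)
    for (int y = 0; y < d.ny; ++y) {
      for (int z = 0; z < d.nz; ++z) f[z] = out[d.idx(z, y, x)];
      dt1d(f, d.nz, spacing[0], dst, v, zb);
      for (int z = 0; z < d.nz; ++z) {
        double dface = std::min((double)(z + 1), (double)(d.nz - z)) * spacing[0];
        out[d.idx(z, y, x)] = std::min(dst[z], dface * dface);
      }
    }
  // pass along y
  for (int x = 0; x < d.nx; ++x)
    for (int z = 0; z < d.nz; ++z) {
      for (int y = 0; y < d.ny; ++y) f[y] = out[d.idx(z, y, x)];
      dt1d(f, d.ny, spacing[1], dst, v, zb);
      for (int y = 0; y < d.ny; ++y) {
        double dface = std::min((double)(y + 1), (double)(d.ny - y)) * spacing[1];
        out[d.idx(z, y, x)] = std::min(dst[y], dface * dface);
      }
    }
  // pass along x
  for (int y = 0; y < d.ny; ++y)
    for (int z = 0; z < d.nz; ++z) {
      for (int x = 0; x < d.nx; ++x) f[x] = out[d.idx(z, y, x)];
      dt1d(f, d.nx, spacing[2], dst, v, zb);
      for (int x = 0; x < d.nx; ++x) {
        double dface = std::min((double)(x + 1), (double)(d.nx - x)) * spacing[2];
        out[d.idx(z, y, x)] = std::min(dst[x], dface * dface);
      }
    }
  return out;
}

// Marker-based watershed by priority flooding of a height map (higher
// floods first; pass the distance transform to split at necks).
// [[Rcpp::export(name = ".watershed3d")]]
IntegerVector watershed3d(NumericVector height, IntegerVector markers,
                          LogicalVector mask, IntegerVector dims, int connectivity) {
  Dims d = as_dims(dims);
  long n = d.n();
  if ((long)height.size() != n || (long)markers.size() != n || (long)mask.size() != n)
    stop("length mismatch");
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  IntegerVector labels(clone(markers));
  typedef std::pair<double, long> Node;
  std::priority_queue<Node> pq;
  for (long i = 0; i < n; ++i)
    if (labels[i] > 0 && mask[i]) pq.push(Node(height[i], i));
  while (!pq.empty()) {
    long cur = pq.top().second;
    pq.pop();
    int cz = (int)(cur % d.nz);
    long rest = cur / d.nz;
    int cy = (int)(rest % d.ny);
    int cx = (int)(rest / d.ny);
    int lab = labels[cur];
    for (const auto &o : off) {
      int nz2 = cz + o[0], ny2 = cy + o[1], nx2 = cx + o[2];
      if (nz2 < 0 || ny2 < 0 || nx2 < 0 || nz2 >= d.nz || ny2 >= d.ny || nx2 >= d.nx)
        continue;
      long j = d.idx(nz2, ny2, nx2);
      if (mask[j] && labels[j] == 0) {
        labels[j] = lab;
        pq.push(Node(height[j], j));
      }
    }
  }
  return labels;
}
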