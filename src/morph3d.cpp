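// Low-level 3D grid primitives shared by the segmentation pipeline.
// All arrays are column-major with dim = c(nx, ny, nz); linear indices
// are 0-based here and converted at the R boundary.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  explicit Grid(const IntegerVector& d) : nx(d[0]), ny(d[1]), nz(d[2]) {}
  R_xlen_t size() const {
    return (R_xlen_t)nx * (R_xlen_t)ny * (R_xlen_t)nz;
  }
  R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  }
  bool inside(int i, int j, int k) const {
    return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
  }
  void coords(R_xlen_t v, int& i, int& j, int& k) const {
    i = (int)(v % nx);
    R_xlen_t r = v / nx;
    j = (int)(r % ny);
    k = (int)(r / ny);
  }
};

// the 26 lattice directions (all nonzero offsets in {-1,0,1}^3)
struct Neigh26 {
  int d[26][3];
  Neigh26() {
    int n = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          d[n][0] = dx; d[n][1] = dy; d[n][2] = dz; ++n;
        }
  }
};
static const Neigh26 NB;

const double DT_INF = 1e30;

// Felzenszwalb & Huttenlocher 1D squared distance transform on a
// sampled line with sample step w (anisotropic spacing support).
void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double w,
          std::vector<int>& v, std::vector<double>& z) {
  const double inf = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -inf;
  z[1] = inf;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    for (;;) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

} // namespace

// Squared Euclidean distance (in the units of `spacing`) from every voxel
// to the nearest TRUE voxel of `mask`.  Voxels of an empty mask get DT_INF.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  Grid g(dim);
  R_xlen_t n = g.size();
  NumericVector out(n);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = mask[v] ? 0.0 : DT_INF;

  int nmax = std::max(g.nx, std::max(g.ny, g.nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> vv(nmax);

  // pass along x
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j) {
      for (int i = 0; i < g.nx; ++i) f[i] = out[g.idx(i, j, k)];
      dt1d(f, d, g.nx, spacing[0], vv, z);
      for (int i = 0; i < g.nx; ++i) out[g.idx(i, j, k)] = d[i];
    }
  // pass along y
  for (int k = 0; k < g.nz; ++k)
    for (int i = 0; i < g.nx; ++i) {
      for (int j = 0; j < g.ny; ++j) f[j] = out[g.idx(i, j, k)];
      dt1d(f, d, g.ny, spacing[1], vv, z);
      for (int j = 0; j < g.ny; ++j) out[g.idx(i, j, k)] = d[j];
    }
  // pass along z
  for (int j = 0; j < g.ny; ++j)
    for (int i = 0; i < g.nx; ++i) {
      for (int k = 0; k < g.nz; ++k) f[k] = out[g.idx(i, j, k)];
      dt1d(f, d, g.nz, spacing[2], vv, z);
      for (int k = 0; k < g.nz; ++k) out[g.idx(i, j, k)] = d[k];
    }
  return out;
}

// 26-connected component labelling; labels are 1..n in decreasing order
// of discovery only (use cpp_component_sizes/tabulate in R for ranking).
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = g.size();
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i, j, k;
      g.coords(v, i, j, k);
      for (int t = 0; t < 26; ++t) {
        int ii = i + NB.d[t][0], jj = j + NB.d[t][1], kk = k + NB.d[t][2];
        if (!g.inside(ii, jj, kk)) continue;
        R_xlen_t w = g.idx(ii, jj, kk);
        if (mask[w] && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// 26-connected volume growing: BFS from `seeds0` (0-based linear indices,
// always included) into voxels where `accept` is TRUE.
// [[Rcpp::export]]
LogicalVector cpp_region_grow26(LogicalVector accept, IntegerVector seeds0,
                                IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = g.size();
  LogicalVector grown(n, false);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < seeds0.size(); ++s) {
    R_xlen_t v = seeds0[s];
    if (v < 0 || v >= n) stop("seed index out of range");
    if (!grown[v]) {
      grown[v] = true;
      stack.push_back(v);
    }
  }
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int i, j, k;
    g.coords(v, i, j, k);
    for (int t = 0; t < 26; ++t) {
      int ii = i + NB.d[t][0], jj = j + NB.d[t][1], kk = k + NB.d[t][2];
      if (!g.inside(ii, jj, kk)) continue;
      R_xlen_t w = g.idx(ii, jj, kk);
      if (!grown[w] && accept[w]) {
        grown[w] = true;
        stack.push_back(w);
      }
    }
  }
  return grown;
}

// Count, for every voxel, its 26-neighbours that are inside the grid,
// `valid`, and have x >= thr.  Out-of-grid / invalid neighbours count as
// failing (the conservative convention of the aggregation map).
// [[Rcpp::export]]
IntegerVector cpp_count_neighbors_ge(NumericVector x, double thr,
                                     LogicalVector valid, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = g.size();
  IntegerVector cnt(n, 0);
  for (R_xlen_t v = 0; v < n; ++v) {
    int i, j, k;
    g.coords(v, i, j, k);
    int c = 0;
    for (int t = 0; t < 26; ++t) {
      int ii = i + NB.d[t][0], jj = j + NB.d[t][1], kk = k + NB.d[t][2];
      if (!g.inside(ii, jj, kk)) continue;
      R_xlen_t w = g.idx(ii, jj, kk);
      if (valid[w] && x[w] >= thr) ++c;
    }
    cnt[v] = c;
  }
  return cnt;
}

// Mean and (sample) SD of the 26-neighbourhood values of every voxel.
// Neighbours outside the grid are simply absent from the statistic.
// [[Rcpp::export]]
List cpp_neighbor_mean_sd(NumericVector x, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = g.size();
  NumericVector mu(n), sd(n);
  for (R_xlen_t v = 0; v < n; ++v) {
    int i, j, k;
    g.coords(v, i, j, k);
    double s = 0.0, s2 = 0.0;
    int m = 0;
    for (int t = 0; t < 26; ++t) {
      int ii = i + NB.d[t][0], jj = j + NB.d[t][1], kk = k + NB.d[t][2];
      if (!g.inside(ii, jj, kk)) continue;
      double val = x[g.idx(ii, jj, kk)];
      s += val;
      s2 += val * val;
      ++m;
    }
    double mean = s / m;
    mu[v] = mean;
    double var = m > 1 ? (s2 - m * mean * mean) / (m - 1) : 0.0;
    sd[v] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// Ray-reflection shielding.  The gap is grown (26-connected) from the
// seeds through voxels that are in `band` but neither blocker; every
// visited voxel casts 26 integer-lattice rays with unit voxel steps.
// A ray reflects when it reaches a blocker voxel before its Euclidean
// length exceeds `maxlen` voxels or it leaves the band/grid.
// status: 0 untested, 1 visited & not shielded, 2 visited & shielded.
// [[Rcpp::export]]
List cpp_ray_shield(LogicalVector blocker, LogicalVector band,
                    IntegerVector seeds0, IntegerVector dim,
                    int quorum, double maxlen) {
  Grid g(dim);
  R_xlen_t n = g.size();
  IntegerVector status(n, 0);
  IntegerVector nref(n, -1);
  std::vector<R_xlen_t> stack;
  std::vector<char> visited(n, 0);
  for (R_xlen_t s = 0; s < seeds0.size(); ++s) {
    R_xlen_t v = seeds0[s];
    if (v < 0 || v >= n) stop("seed index out of range");
    if (blocker[v]) stop("shielding seed lies on the fascia approximation or a candidate voxel");
    if (!visited[v]) {
      visited[v] = 1;
      stack.push_back(v);
    }
  }
  double steplen[26];
  for (int t = 0; t < 26; ++t)
    steplen[t] = std::sqrt((double)(NB.d[t][0] * NB.d[t][0] +
                                    NB.d[t][1] * NB.d[t][1] +
                                    NB.d[t][2] * NB.d[t][2]));
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int i, j, k;
    g.coords(v, i, j, k);
    int refl = 0;
    for (int t = 0; t < 26; ++t) {
      int ii = i, jj = j, kk = k;
      double len = 0.0;
      for (;;) {
        ii += NB.d[t][0]; jj += NB.d[t][1]; kk += NB.d[t][2];
        len += steplen[t];
        if (len > maxlen) break;
        if (!g.inside(ii, jj, kk)) break;
        R_xlen_t w = g.idx(ii, jj, kk);
        if (blocker[w]) { ++refl; break; }
        if (!band[w]) break;
      }
    }
    nref[v] = refl;
    status[v] = refl >= quorum ? 2 : 1;
    for (int t = 0; t < 26; ++t) {
      int ii = i + NB.d[t][0], jj = j + NB.d[t][1], kk = k + NB.d[t][2];
      if (!g.inside(ii, jj, kk)) continue;
      R_xlen_t w = g.idx(ii, jj, kk);
      if (!visited[w] && band[w] && !blocker[w]) {
        visited[w] = 1;
        stack.push_back(w);
      }
    }
  }
  return List::create(_["status"] = status, _["reflections"] = nref);
}

namespace {
// 2D 4-connected flood fill of FALSE voxels of slice k reachable from the
// slice border; marks `reach`.
void flood_slice(const LogicalVector& mask, const Grid& g, int k,
                 std::vector<char>& reach, std::vector<R_xlen_t>& stack) {
  std::fill(reach.begin(), reach.end(), 0);
  stack.clear();
  R_xlen_t base = (R_xlen_t)g.nx * g.ny * k;
  for (int i = 0; i < g.nx; ++i)
    for (int j : {0, g.ny - 1}) {
      R_xlen_t p = (R_xlen_t)i + (R_xlen_t)g.nx * j;
      if (!mask[base + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
    }
  for (int j = 0; j < g.ny; ++j)
    for (int i : {0, g.nx - 1}) {
      R_xlen_t p = (R_xlen_t)i + (R_xlen_t)g.nx * j;
      if (!mask[base + p] && !reach[p]) { reach[p] = 1; stack.push_back(p); }
    }
  const int d4[4][2] = {{1, 0}, {-1, 0}, {0, 1}, {0, -1}};
  while (!stack.empty()) {
    R_xlen_t p = stack.back();
    stack.pop_back();
    int i = (int)(p % g.nx), j = (int)(p / g.nx);
    for (auto& dd : d4) {
      int ii = i + dd[0], jj = j + dd[1];
      if (ii < 0 || ii >= g.nx || jj < 0 || jj >= g.ny) continue;
      R_xlen_t q = (R_xlen_t)ii + (R_xlen_t)g.nx * jj;
      if (!mask[base + q] && !reach[q]) { reach[q] = 1; stack.push_back(q); }
    }
  }
}
} // namespace

// Per-slice (xy) cavity filling: background voxels not 4-connected to the
// slice border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_slices(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)g.nx * g.ny);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < g.nz; ++k) {
    flood_slice(mask, g, k, reach, stack);
    R_xlen_t base = (R_xlen_t)g.nx * g.ny * k;
    for (R_xlen_t p = 0; p < (R_xlen_t)g.nx * g.ny; ++p)
      if (!mask[base + p] && !reach[p]) out[base + p] = true;
  }
  return out;
}

// Full 3D cavity filling: background voxels not 6-connected to the volume
// border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_3d(LogicalVector mask, IntegerVector dim) {
  Grid g(dim);
  R_xlen_t n = g.size();
  std::vector<char> reach(n, 0);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        if (i != 0 && i != g.nx - 1 && j != 0 && j != g.ny - 1 &&
            k != 0 && k != g.nz - 1)
          continue;
        R_xlen_t v = g.idx(i, j, k);
        if (!mask[v] && !reach[v]) { reach[v] = 1; stack.push_back(v); }
      }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    R_xlen_t v = stack.back();
    stack.pop_back();
    int i, j, k;
    g.coords(v, i, j, k);
    for (auto& dd : d6) {
      int ii = i + dd[0], jj = j + dd[1], kk = k + dd[2];
      if (!g.inside(ii, jj, kk)) continue;
      R_xlen_t w = g.idx(ii, jj, kk);
      if (!mask[w] && !reach[w]) { reach[w] = 1; stack.push_back(w); }
    }
  }
  LogicalVector out = clone(mask);
  for (R_xlen_t v = 0; v < n; ++v)
    if (!mask[v] && !reach[v]) out[v] = true;
  return out;
}
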