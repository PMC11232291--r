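#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Spatial hash grid over 3D points. Cell size must be >= any query radius so
// a 27-cell neighbourhood suffices.
struct HashGrid {
  double cell, x0, y0, z0;
  std::unordered_map<long long, std::vector<int> > cells;

  static long long key3(long long ix, long long iy, long long iz) {
    return ix + (iy << 21) + (iz << 42);
  }
  void build(const NumericMatrix& pts, double cell_size) {
    cell = cell_size;
    int n = pts.nrow();
    x0 = y0 = z0 = R_PosInf;
    for (int i = 0; i < n; ++i) {
      if (pts(i, 0) < x0) x0 = pts(i, 0);
      if (pts(i, 1) < y0) y0 = pts(i, 1);
      if (pts(i, 2) < z0) z0 = pts(i, 2);
    }
    cells.reserve(n);
    for (int i = 0; i < n; ++i) cells[key(pts, i)].push_back(i);
  }
  long long key(const NumericMatrix& pts, int i) const {
    long long ix = (long long)std::floor((pts(i, 0) - x0) / cell);
    long long iy = (long long)std::floor((pts(i, 1) - y0) / cell);
    long long iz = (long long)std::floor((pts(i, 2) - z0) / cell);
    return key3(ix, iy, iz);
  }
  // visit point indices in the 27-cell neighbourhood of point i
  template <typename F>
  void neighbours(const NumericMatrix& pts, int i, F fun) const {
    long long ix = (long long)std::floor((pts(i, 0) - x0) / cell);
    long long iy = (long long)std::floor((pts(i, 1) - y0) / cell);
    long long iz = (long long)std::floor((pts(i, 2) - z0) / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            cells.find(key3(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t k = 0; k < v.size(); ++k) fun(v[k]);
        }
  }
};

static inline double dist2(const NumericMatrix& p, int i, int j) {
  double dx = p(i, 0) - p(j, 0), dy = p(i, 1) - p(j, 1), dz = p(i, 2) - p(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// Greedy ball covering: walk points in `order` (1-based permutation); each
// still-uncovered point seeds a patch that claims all uncovered points within
// `radius`. Patch adjacency: an inter-patch point pair within `adj_dist`.
// [[Rcpp::export]]
List cpp_generate_cover(NumericMatrix pts, double radius, double adj_dist,
                        IntegerVector order) {
  int n = pts.nrow();
  double cell = std::max(radius, adj_dist);
  HashGrid grid;
  grid.build(pts, cell);

  IntegerVector patch(n, 0);
  std::vector<int> seeds;
  double r2 = radius * radius;
  for (int k = 0; k < n; ++k) {
    int i = order[k] - 1;
    if (patch[i] != 0) continue;
    int id = (int)seeds.size() + 1;
    seeds.push_back(i + 1);
    patch[i] = id;
    grid.neighbours(pts, i, [&](int j) {
      if (patch[j] == 0 && dist2(pts, i, j) <= r2) patch[j] = id;
    });
  }
  int npatch = (int)seeds.size();

  // adjacency between patches
  std::unordered_set<long long> edges;
  double a2 = adj_dist * adj_dist;
  long long P = npatch + 1;
  for (int i = 0; i < n; ++i) {
    grid.neighbours(pts, i, [&](int j) {
      if (j <= i) return;
      if (patch[i] == patch[j]) return;
      if (dist2(pts, i, j) <= a2) {
        long long a = patch[i], b = patch[j];
        if (a > b) std::swap(a, b);
        edges.insert(a * P + b);
      }
    });
  }
  IntegerMatrix em((int)edges.size(), 2);
  int row = 0;
  for (std::unordered_set<long long>::iterator it = edges.begin();
       it != edges.end(); ++it, ++row) {
    em(row, 0) = (int)(*it / P);
    em(row, 1) = (int)(*it % P);
  }
  return List::create(_["patch"] = patch,
                      _["seeds"] = wrap(seeds),
                      _["edges"] = em,
                      _["n_patches"] = npatch);
}

struct DSU {
  std::vector<int> par;
  DSU(int n) : par(n) { for (int i = 0; i < n; ++i) par[i] = i; }
  int find(int x) { while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; } return x; }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    par[b] = a;
    return true;
  }
};

// Bridge occlusion gaps between connected components of the patch graph:
// minimum-distance spanning edges (Kruskal) over nearest inter-component
// centroid pairs, capped at max_gap. Returns the extra edges (1-based).
// [[Rcpp::export]]
IntegerMatrix cpp_bridge_components(NumericMatrix centers, IntegerMatrix edges,
                                    double max_gap) {
  int n = centers.nrow();
  DSU dsu(n);
  for (int e = 0; e < edges.nrow(); ++e)
    dsu.unite(edges(e, 0) - 1, edges(e, 1) - 1);

  HashGrid grid;
  grid.build(centers, max_gap);
  struct Cand { double d; int i, j; };
  std::vector<Cand> cands;
  double g2 = max_gap * max_gap;
  for (int i = 0; i < n; ++i) {
    grid.neighbours(centers, i, [&](int j) {
      if (j <= i) return;
      if (dsu.find(i) == dsu.find(j)) return;
      double d2 = dist2(centers, i, j);
      if (d2 <= g2) cands.push_back({d2, i, j});
    });
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.d != b.d) return a.d < b.d;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  std::vector<std::pair<int, int> > picked;
  for (size_t k = 0; k < cands.size(); ++k)
    if (dsu.unite(cands[k].i, cands[k].j))
      picked.push_back(std::make_pair(cands[k].i + 1, cands[k].j + 1));
  IntegerMatrix out((int)picked.size(), 2);
  for (size_t k = 0; k < picked.size(); ++k) {
    out(k, 0) = picked[k].first;
    out(k, 1) = picked[k].second;
  }
  return out;
}
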