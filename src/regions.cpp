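#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

namespace {

struct DisjointSet {
  std::vector<int> parent, rnk, sz;
  explicit DisjointSet(int n) : parent(n), rnk(n, 0), sz(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  int unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    if (rnk[a] < rnk[b]) std::swap(a, b);
    parent[b] = a;
    sz[a] += sz[b];
    if (rnk[a] == rnk[b]) ++rnk[a];
    return a;
  }
};

struct Edge {
  float w;
  int a, b;
};

}  // namespace

// Efficient graph-based region merging (Felzenszwalb-Huttenlocher style) on
// a grayscale image. 8-connected grid edges weighted by absolute intensity
// difference; components merge while the joining edge is below the adaptive
// internal-difference threshold Int(C) + k/|C|; a final pass absorbs
// components smaller than min_size across their cheapest boundary edge.
// Returns 1-based region labels.
// [[Rcpp::export]]
IntegerMatrix fh_segment_cpp(NumericMatrix img, double k, int min_size) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<Edge> edges;
  edges.reserve(4 * (size_t)n);
  auto idx = [&](int r, int c) { return r + nr * c; };
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double v = img(r, c);
      if (r + 1 < nr)
        edges.push_back({(float)std::fabs(v - img(r + 1, c)), idx(r, c), idx(r + 1, c)});
      if (c + 1 < nc)
        edges.push_back({(float)std::fabs(v - img(r, c + 1)), idx(r, c), idx(r, c + 1)});
      if (r + 1 < nr && c + 1 < nc)
        edges.push_back({(float)std::fabs(v - img(r + 1, c + 1)), idx(r, c), idx(r + 1, c + 1)});
      if (r + 1 < nr && c - 1 >= 0)
        edges.push_back({(float)std::fabs(v - img(r + 1, c - 1)), idx(r, c), idx(r + 1, c - 1)});
    }
  }
  std::sort(edges.begin(), edges.end(),
            [](const Edge& x, const Edge& y) { return x.w < y.w; });

  DisjointSet ds(n);
  std::vector<float> internal(n, 0.0f);  // max MST edge within component
  for (const Edge& e : edges) {
    int a = ds.find(e.a), b = ds.find(e.b);
    if (a == b) continue;
    const double ta = internal[a] + k / ds.sz[a];
    const double tb = internal[b] + k / ds.sz[b];
    if (e.w <= ta && e.w <= tb) {
      int root = ds.unite(a, b);
      internal[root] = e.w;
    }
  }
  // absorb small components
  for (const Edge& e : edges) {
    int a = ds.find(e.a), b = ds.find(e.b);
    if (a != b && (ds.sz[a] < min_size || ds.sz[b] < min_size)) ds.unite(a, b);
  }

  IntegerMatrix labels(nr, nc);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int root = ds.find(idx(r, c));
      if (!remap[root]) remap[root] = ++next;
      labels(r, c) = remap[root];
    }
  return labels;
}

// 8-connected component labelling of a 0/1 mask; background stays 0,
// components numbered 1..k in scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        const int cr = q.front().first, cc = q.front().second;
        q.pop();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            const int rr = cr + dr, c2 = cc + dc;
            if (rr < 0 || c2 < 0 || rr >= nr || c2 >= nc) continue;
            if (mask(rr, c2) && !lab(rr, c2)) {
              lab(rr, c2) = next;
              q.push(std::make_pair(rr, c2));
            }
          }
      }
    }
  }
  return lab;
}

// Multi-source BFS label propagation: every 1-pixel of `mask` receives the
// label of its nearest seeded pixel (seeds = nonzero entries of `labels`),
// distance measured by 8-connected hops within the full image plane.
// [[Rcpp::export]]
IntegerMatrix propagate_labels_cpp(IntegerMatrix labels, IntegerMatrix mask) {
  const int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out(nr, nc);
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (labels(r, c)) {
        out(r, c) = labels(r, c);
        q.push(std::make_pair(r, c));
      }
  while (!q.empty()) {
    const int cr = q.front().first, cc = q.front().second;
    q.pop();
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        const int rr = cr + dr, c2 = cc + dc;
        if (rr < 0 || c2 < 0 || rr >= nr || c2 >= nc) continue;
        if (!out(rr, c2)) {
          out(rr, c2) = out(cr, cc);
          q.push(std::make_pair(rr, c2));
        }
      }
  }
  // restrict to the mask
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (!mask(r, c)) out(r, c) = 0;
  return out;
}
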