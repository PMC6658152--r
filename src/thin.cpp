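#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen topology-preserving thinning. Input: 0/1 matrix. Output: 0/1
// matrix with centerlines ~1 pixel wide; 8-connectivity of each component is
// preserved. Border pixels are handled by treating off-image as background.
// [[Rcpp::export]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);

  auto at = [&](int r, int c) -> int {
    if (r < 0 || c < 0 || r >= nr || c >= nc) return 0;
    return img(r, c) != 0;
  };

  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          // P2..P9 clockwise from north; rows grow downward
          const int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          const int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          const int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          const int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          const int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int a = 0;
          for (int i = 0; i < 8; ++i)
            if (seq[i] == 0 && seq[i + 1] == 1) ++a;
          if (a != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i)
          img(kill[i].first, kill[i].second) = 0;
      }
    }
  }

  // minimality cleanup: remove every non-tip pixel whose set neighbours are
  // still one 8-connected cluster without it (an 8-simple point). Zhang-Suen
  // leaves redundant corners and run-end pixels on shallow diagonals that
  // would masquerade as junctions; sequential removal with live updates
  // keeps connectivity intact and yields a minimal centerline.
  bool removed = true;
  while (removed) {
    removed = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!img(r, c)) continue;
        int n = 0;
        int pr[8], pc[8];
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            if (at(r + dr, c + dc)) {
              pr[n] = dr; pc[n] = dc; ++n;
            }
          }
        if (n < 2) continue;  // tips and isolated pixels stay
        // single-linkage over the set neighbours (Chebyshev adjacency,
        // never through the centre pixel)
        int comp[8];
        for (int i = 0; i < n; ++i) comp[i] = i;
        bool merged = true;
        while (merged) {
          merged = false;
          for (int i = 0; i < n; ++i)
            for (int j = i + 1; j < n; ++j) {
              if (comp[i] == comp[j]) continue;
              if (std::abs(pr[i] - pr[j]) <= 1 &&
                  std::abs(pc[i] - pc[j]) <= 1) {
                const int from = comp[j], to = comp[i];
                for (int k = 0; k < n; ++k)
                  if (comp[k] == from) comp[k] = to;
                merged = true;
              }
            }
        }
        bool one_cluster = true;
        for (int i = 1; i < n; ++i)
          if (comp[i] != comp[0]) { one_cluster = false; break; }
        if (one_cluster) {
          img(r, c) = 0;
          removed = true;
        }
      }
    }
  }
  return img;
}
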