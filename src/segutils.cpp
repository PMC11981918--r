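// Face-graph utilities for thickness segmentation: edge-adjacency, label
// mode smoothing, and same-label connected components.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <queue>
#include <cstdint>

using namespace Rcpp;

// adjacency over shared undirected edges; at most 3 neighbors per face on a
// manifold mesh. Returns an nf x 3 matrix of 1-based face ids (0 = none).
// [[Rcpp::export(name = ".cpp_face_adjacency")]]
IntegerMatrix cpp_face_adjacency(IntegerMatrix F, int n_vertices) {
  int nf = F.nrow();
  std::unordered_map<int64_t, int> first_face;
  first_face.reserve(nf * 3);
  IntegerMatrix adj(nf, 3);
  std::vector<int> deg(nf, 0);
  for (int f = 0; f < nf; ++f) {
    for (int e = 0; e < 3; ++e) {
      int a = F(f, e), b = F(f, (e + 1) % 3);
      if (a > b) std::swap(a, b);
      int64_t key = (int64_t)a * (n_vertices + 1) + b;
      auto it = first_face.find(key);
      if (it == first_face.end()) {
        first_face[key] = f;
      } else {
        int g = it->second;
        if (g >= 0) {
          if (deg[f] < 3) adj(f, deg[f]++) = g + 1;
          if (deg[g] < 3) adj(g, deg[g]++) = f + 1;
          it->second = -1;  // manifold edge consumed
        }
      }
    }
  }
  return adj;
}

// iterative mode filter of integer labels over the face adjacency
// [[Rcpp::export(name = ".cpp_mode_smooth")]]
IntegerVector cpp_mode_smooth(IntegerMatrix adj, IntegerVector labels, int iters) {
  int nf = adj.nrow();
  std::vector<int> cur(labels.begin(), labels.end()), nxt(nf);
  int maxlab = 0;
  for (int i = 0; i < nf; ++i) maxlab = std::max(maxlab, cur[i]);
  std::vector<int> count(maxlab + 1, 0);
  for (int it = 0; it < iters; ++it) {
    for (int f = 0; f < nf; ++f) {
      std::fill(count.begin(), count.end(), 0);
      count[cur[f]]++;
      for (int j = 0; j < 3; ++j) {
        int g = adj(f, j);
        if (g > 0) count[cur[g - 1]]++;
      }
      int best = cur[f];
      for (int l = 1; l <= maxlab; ++l) {
        if (count[l] > count[best]) best = l;
      }
      nxt[f] = best;
    }
    cur.swap(nxt);
  }
  return IntegerVector(cur.begin(), cur.end());
}

// connected components among faces sharing the same label (edge-connected)
// [[Rcpp::export(name = ".cpp_label_face_components")]]
IntegerVector cpp_label_face_components(IntegerMatrix adj, IntegerVector labels) {
  int nf = adj.nrow();
  IntegerVector comp(nf, 0);
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < nf; ++s) {
    if (comp[s] != 0) continue;
    comp[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      int f = q.front(); q.pop();
      for (int j = 0; j < 3; ++j) {
        int g = adj(f, j) - 1;
        if (g >= 0 && comp[g] == 0 && labels[g] == labels[f]) {
          comp[g] = next;
          q.push(g);
        }
      }
    }
  }
  return comp;
}
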