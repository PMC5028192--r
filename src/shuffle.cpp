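// Uniform dinucleotide-preserving shuffle (Altschul-Erickson style).
//
// The sequence is an Eulerian path on the 4-vertex dinucleotide multigraph.
// A uniform random Euler path with fixed endpoints is drawn by (1) picking a
// uniform "last exit" edge for every vertex except the terminal one and
// rejecting until the chosen edges form an arborescence into the terminal
// vertex, then (2) uniformly permuting each vertex's remaining out-edges and
// walking the path. Uses R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
CharacterVector c_dinuc_shuffle(IntegerVector s, int n_out) {
  const char ABC[5] = "ACGU";
  int n = s.size();
  std::vector<std::vector<int>> adj(4);
  for (int t = 0; t + 1 < n; ++t) adj[s[t]].push_back(s[t + 1]);
  int start = s[0], end = s[n - 1];
  CharacterVector out(n_out);
  std::vector<int> lastx(4, -1), ptr(4);
  std::vector<std::vector<int>> ord(4);
  std::string buf(n, 'A');
  for (int r = 0; r < n_out; ++r) {
    // choose last-exit edges until they form an in-tree to `end`
    bool ok = false;
    for (int tries = 0; tries < 100000 && !ok; ++tries) {
      for (int v = 0; v < 4; ++v)
        lastx[v] = (v != end && !adj[v].empty()) ? adj[v][rand_below(adj[v].size())] : -1;
      ok = true;
      for (int v = 0; v < 4 && ok; ++v) {
        if (v == end || adj[v].empty()) continue;
        int cur = v;
        int steps = 0;
        while (cur != end && steps < 5) {
          cur = lastx[cur];
          if (cur < 0 || (cur != end && adj[cur].empty())) break;
          ++steps;
        }
        if (cur != end) ok = false;
      }
    }
    if (!ok) stop("failed to sample an Eulerian arborescence");
    for (int v = 0; v < 4; ++v) {
      ord[v] = adj[v];
      if (lastx[v] >= 0) {
        // remove one instance of the last-exit target, re-append after shuffle
        for (size_t t = 0; t < ord[v].size(); ++t)
          if (ord[v][t] == lastx[v]) { ord[v].erase(ord[v].begin() + t); break; }
      }
      for (int t = (int)ord[v].size() - 1; t > 0; --t)
        std::swap(ord[v][t], ord[v][rand_below(t + 1)]);
      if (lastx[v] >= 0) ord[v].push_back(lastx[v]);
      ptr[v] = 0;
    }
    int cur = start;
    buf[0] = ABC[cur];
    for (int t = 1; t < n; ++t) {
      int nx = ord[cur][ptr[cur]++];
      buf[t] = ABC[nx];
      cur = nx;
    }
    out[r] = buf;
  }
  return out;
}
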