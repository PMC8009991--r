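#include <Rcpp.h>
#include <vector>
#include <unordered_set>
using namespace Rcpp;

// All-pairs shortest paths (Floyd-Warshall) on a matrix of edge lengths.
// `len` holds 1/weight for edges and R_PosInf for non-edges; diagonal 0.
// [[Rcpp::export(name = ".fw_dist")]]
NumericMatrix fw_dist(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix d(clone(len));
  for (int i = 0; i < n; ++i) d(i, i) = 0.0;
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

// Maslov-Sneppen degree-preserving double-edge swaps on an undirected
// edge list (1-based node indices, m x 2). Weights travel with rows, so the
// weight multiset is preserved by construction. Uses R's RNG (seedable via
// set.seed). Returns the rewired edge list; attribute "accepted" counts
// accepted swaps.
// [[Rcpp::export(name = ".ms_rewire")]]
IntegerMatrix ms_rewire(IntegerMatrix edges, int n_nodes, int target_swaps,
                        int max_attempts) {
  int m = edges.nrow();
  IntegerMatrix e(clone(edges));
  std::vector< std::unordered_set<int> > adj(n_nodes + 1);
  for (int r = 0; r < m; ++r) {
    adj[e(r, 0)].insert(e(r, 1));
    adj[e(r, 1)].insert(e(r, 0));
  }
  int accepted = 0, attempts = 0;
  while (accepted < target_swaps && attempts < max_attempts) {
    ++attempts;
    int r1 = (int)(unif_rand() * m);
    int r2 = (int)(unif_rand() * m);
    if (r1 == r2) continue;
    int a = e(r1, 0), b = e(r1, 1), c = e(r2, 0), d = e(r2, 1);
    // optionally flip the second edge to vary the pairing
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    // proposed: (a,d) and (c,b)
    if (a == d || c == b || a == c || b == d) continue;
    if (adj[a].count(d) || adj[c].count(b)) continue;
    adj[a].erase(b); adj[b].erase(a);
    adj[c].erase(d); adj[d].erase(c);
    adj[a].insert(d); adj[d].insert(a);
    adj[c].insert(b); adj[b].insert(c);
    e(r1, 0) = a; e(r1, 1) = d;
    e(r2, 0) = c; e(r2, 1) = b;
    ++accepted;
  }
  e.attr("accepted") = accepted;
  return e;
}
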