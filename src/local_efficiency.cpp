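#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local efficiency of a binary undirected graph: mean over nodes of the
// global efficiency of the subgraph induced by each node's neighbours.
// BFS per neighbour inside the (small) neighbourhood subgraph; nodes with
// fewer than 2 neighbours contribute 0.
// [[Rcpp::export]]
double cpp_local_efficiency(const IntegerMatrix& A) {
  const int n = A.nrow();
  if (n == 0) return 0.0;
  double total = 0.0;
  std::vector<int> nb;
  nb.reserve(n);
  std::vector<int> dist, queue;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (A(i, j)) nb.push_back(j);
    }
    const int k = static_cast<int>(nb.size());
    if (k < 2) continue;
    dist.assign(k, -1);
    queue.assign(k, 0);
    double eff = 0.0;
    for (int s = 0; s < k; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      dist[s] = 0;
      int qh = 0, qt = 0;
      queue[qt++] = s;
      while (qh < qt) {
        const int u = queue[qh++];
        const int gu = nb[u];
        for (int b = 0; b < k; ++b) {
          if (dist[b] < 0 && A(gu, nb[b])) {
            dist[b] = dist[u] + 1;
            queue[qt++] = b;
          }
        }
      }
      for (int b = 0; b < k; ++b) {
        if (b != s && dist[b] > 0) eff += 1.0 / dist[b];
      }
    }
    total += eff / (static_cast<double>(k) * (k - 1));
  }
  return total / n;
}
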