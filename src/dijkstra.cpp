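#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// Multi-source Dijkstra on an undirected weighted graph.
//
// Edges are given once (from/to 0-based); both directions are expanded here.
// All sources start at time 0.  Ties in the priority queue are broken by
// (time, node index) so repeated runs are bit-identical.
//
// [[Rcpp::export(name = ".dijkstra_cpp")]]
NumericVector dijkstra_cpp(const int n_nodes,
                           const IntegerVector& from,
                           const IntegerVector& to,
                           const NumericVector& weight,
                           const IntegerVector& sources) {
  const int m = from.size();
  if (to.size() != m || weight.size() != m)
    stop("edge arrays must have equal length");

  // CSR-style adjacency for the doubled edge list
  std::vector<int> deg(n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    if (a < 0 || a >= n_nodes || b < 0 || b >= n_nodes)
      stop("edge endpoint out of range");
    if (weight[e] <= 0 || !R_finite(weight[e]))
      stop("edge weights must be positive and finite");
    deg[a]++; deg[b]++;
  }
  std::vector<int> ptr(n_nodes + 1, 0);
  for (int v = 0; v < n_nodes; ++v) ptr[v + 1] = ptr[v] + deg[v];
  std::vector<int> adj_v(2 * (size_t)m);
  std::vector<double> adj_w(2 * (size_t)m);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < m; ++e) {
      int a = from[e], b = to[e];
      adj_v[fill[a]] = b; adj_w[fill[a]] = weight[e]; fill[a]++;
      adj_v[fill[b]] = a; adj_w[fill[b]] = weight[e]; fill[b]++;
    }
  }

  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n_nodes, inf);

  typedef std::pair<double, int> qitem; // (time, node); min-heap
  std::priority_queue<qitem, std::vector<qitem>, std::greater<qitem> > pq;
  for (int s = 0; s < sources.size(); ++s) {
    int v = sources[s];
    if (v < 0 || v >= n_nodes) stop("source node out of range");
    dist[v] = 0.0;
    pq.push(qitem(0.0, v));
  }
  if (pq.empty()) stop("at least one source node is required");

  while (!pq.empty()) {
    qitem top = pq.top(); pq.pop();
    double d = top.first; int v = top.second;
    if (d > dist[v]) continue; // stale entry
    for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
      int u = adj_v[k];
      double nd = d + adj_w[k];
      if (nd < dist[u]) {
        dist[u] = nd;
        pq.push(qitem(nd, u));
      }
    }
  }

  NumericVector out(n_nodes);
  for (int v = 0; v < n_nodes; ++v) out[v] = dist[v];
  return out;
}
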