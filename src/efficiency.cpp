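#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// BFS from one source over an adjacency list; dist = -1 means unreachable.
static void bfs(const std::vector< std::vector<int> >& adj, int src,
                std::vector<int>& dist, std::vector<int>& queue) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[src] = 0;
  int head = 0, tail = 0;
  queue[tail++] = src;
  while (head < tail) {
    int u = queue[head++];
    int du = dist[u];
    for (size_t k = 0; k < adj[u].size(); ++k) {
      int v = adj[u][k];
      if (dist[v] < 0) {
        dist[v] = du + 1;
        queue[tail++] = v;
      }
    }
  }
}

static std::vector< std::vector<int> > adjacency_list(const IntegerMatrix& A) {
  int n = A.nrow();
  std::vector< std::vector<int> > adj(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && A(i, j) != 0) adj[j].push_back(i);
  return adj;
}

// Mean inverse shortest-path length over ordered pairs (disconnected -> 0).
static double geff_from_adjlist(const std::vector< std::vector<int> >& adj) {
  int n = (int) adj.size();
  if (n < 2) return 0.0;
  std::vector<int> dist(n), queue(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist, queue);
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) total += 1.0 / dist[j];
  }
  return total / ((double) n * (n - 1));
}

// [[Rcpp::export(name = ".bfs_distance_matrix")]]
NumericMatrix bfs_distance_matrix(IntegerMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > adj = adjacency_list(A);
  std::vector<int> dist(n), queue(n);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist, queue);
    for (int j = 0; j < n; ++j)
      D(j, i) = (dist[j] < 0) ? R_PosInf : (double) dist[j];
  }
  return D;
}

// [[Rcpp::export(name = ".global_efficiency_cpp")]]
double global_efficiency_cpp(IntegerMatrix A) {
  return geff_from_adjlist(adjacency_list(A));
}

// [[Rcpp::export(name = ".nodal_efficiency_cpp")]]
NumericVector nodal_efficiency_cpp(IntegerMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > adj = adjacency_list(A);
  std::vector<int> dist(n), queue(n);
  NumericVector e(n);
  for (int i = 0; i < n; ++i) {
    bfs(adj, i, dist, queue);
    double total = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && dist[j] > 0) total += 1.0 / dist[j];
    e[i] = total / (double) (n - 1);
  }
  return e;
}

// Local efficiency: mean over nodes of the global efficiency of the
// neighbour-induced subgraph; subgraphs with < 2 nodes contribute 0.
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
double local_efficiency_cpp(IntegerMatrix A) {
  int n = A.nrow();
  std::vector< std::vector<int> > adj = adjacency_list(A);
  std::vector<int> label(n, -1);  // position of node in current subgraph
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& nb = adj[i];
    int m = (int) nb.size();
    if (m < 2) continue;
    for (int k = 0; k < m; ++k) label[nb[k]] = k;
    std::vector< std::vector<int> > sub(m);
    for (int k = 0; k < m; ++k) {
      const std::vector<int>& nbk = adj[nb[k]];
      for (size_t l = 0; l < nbk.size(); ++l)
        if (label[nbk[l]] >= 0 && nbk[l] != nb[k]) sub[k].push_back(label[nbk[l]]);
    }
    total += geff_from_adjlist(sub);
    for (int k = 0; k < m; ++k) label[nb[k]] = -1;
  }
  return total / (double) n;
}
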