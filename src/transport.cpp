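#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact minimum-cost transport between two discrete mass distributions.
//
// Successive-shortest-path min-cost flow on the complete bipartite graph of
// supply nodes (rows of the cost matrix) and demand nodes (columns), with
// Johnson potentials so reduced edge costs stay non-negative. Supplies and
// demands are real-valued; every augmentation saturates at least one supply
// or demand node, so at most m + n - 1 augmentations occur.
//
// a: supplies (length m), b: demands (length n), cost: m x n ground
// distances. sum(a) must equal sum(b) up to rounding. Returns the minimal
// total transport cost.
// [[Rcpp::export(name = ".cpp_transport_cost")]]
double cpp_transport_cost(NumericVector a, NumericVector b,
                          NumericMatrix cost) {
  const int m = a.size(), n = b.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions do not match supplies/demands");
  const double INF = std::numeric_limits<double>::infinity();
  const double EPS = 1e-14;

  std::vector<double> sa(a.begin(), a.end()), sb(b.begin(), b.end());
  double total_a = 0.0, total_b = 0.0;
  for (int i = 0; i < m; ++i) {
    if (sa[i] < -EPS) stop("negative supply");
    total_a += sa[i];
  }
  for (int j = 0; j < n; ++j) {
    if (sb[j] < -EPS) stop("negative demand");
    total_b += sb[j];
  }
  if (std::fabs(total_a - total_b) > 1e-9 * std::max(1.0, total_a))
    stop("supplies and demands must balance");

  // flow stored dense; fine for histogram-sized problems
  std::vector<double> flow((size_t)m * n, 0.0);
  std::vector<double> pot(m + n, 0.0);
  const int N = m + n;
  std::vector<double> dist(N);
  std::vector<int> prev(N);
  std::vector<char> done(N);

  double remaining = total_a;
  while (remaining > 1e-12 * std::max(1.0, total_a)) {
    // Dijkstra from all supply nodes with remaining mass
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(prev.begin(), prev.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    for (int i = 0; i < m; ++i)
      if (sa[i] > EPS) dist[i] = 0.0;

    for (int it = 0; it < N; ++it) {
      int u = -1;
      double best = INF;
      for (int v = 0; v < N; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;
      done[u] = 1;
      if (u < m) {              // supply node: forward edges to all demands
        const double du = dist[u], pu = pot[u];
        for (int j = 0; j < n; ++j) {
          const int v = m + j;
          if (done[v]) continue;
          const double rc = cost(u, j) + pu - pot[v];
          if (du + rc < dist[v] - 1e-15) { dist[v] = du + rc; prev[v] = u; }
        }
      } else {                  // demand node: residual edges back to supplies
        const int j = u - m;
        const double du = dist[u], pu = pot[u];
        for (int i = 0; i < m; ++i) {
          if (done[i] || flow[(size_t)i * n + j] <= EPS) continue;
          const double rc = -cost(i, j) + pu - pot[i];
          if (du + rc < dist[i] - 1e-15) { dist[i] = du + rc; prev[i] = m + j; }
        }
      }
    }

    // closest demand node still needing mass
    int t = -1;
    double bestd = INF;
    for (int j = 0; j < n; ++j)
      if (sb[j] > EPS && dist[m + j] < bestd) { bestd = dist[m + j]; t = m + j; }
    if (t < 0) stop("transport problem infeasible (numerical imbalance)");

    for (int v = 0; v < N; ++v)
      if (dist[v] < INF) pot[v] += std::min(dist[v], bestd);

    // bottleneck along the path
    double delta = sb[t - m];
    int v = t;
    while (prev[v] >= 0) {
      const int u = prev[v];
      if (u < m && v >= m) {
        // forward edge, infinite capacity
      } else {
        // residual edge v->... wait: u is predecessor; edge u -> v
        // u >= m, v < m: residual edge limited by existing flow f[v][u-m]
        delta = std::min(delta, flow[(size_t)v * n + (u - m)]);
      }
      v = u;
    }
    delta = std::min(delta, sa[v]);  // v is the originating supply node
    if (delta <= EPS) stop("degenerate augmentation in transport solver");

    // apply augmentation
    v = t;
    while (prev[v] >= 0) {
      const int u = prev[v];
      if (u < m) flow[(size_t)u * n + (v - m)] += delta;
      else flow[(size_t)v * n + (u - m)] -= delta;
      v = u;
    }
    sa[v] -= delta;
    sb[t - m] -= delta;
    remaining -= delta;
  }

  double total = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      const double f = flow[(size_t)i * n + j];
      if (f > 0) total += f * cost(i, j);
    }
  return total;
}
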