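#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow / min-cut for the s-t voxel graphs built by the
// graph-cut segmenter. BFS builds shortest-path levels from the source;
// DFS pushes blocking flow along level-increasing arcs. On grid graphs
// with a handful of distinct capacity scales this runs in a few dozen
// phases. Terminal capacities are passed per node; after termination the
// source side of the min cut is every node reachable from the source in
// the residual graph.

namespace {

constexpr double EPS = 1e-11;

struct Dinic {
  int n;                       // total nodes incl. source (n-2), sink (n-1)
  std::vector<int> head, nxt, first;
  std::vector<double> cap;
  std::vector<int> level, iter;
  double flow = 0;

  explicit Dinic(int n_) : n(n_), first(n_, -1), level(n_), iter(n_) {}

  void add_edge(int u, int v, double c_uv, double c_vu) {
    head.push_back(v); cap.push_back(c_uv); nxt.push_back(first[u]);
    first[u] = (int)head.size() - 1;
    head.push_back(u); cap.push_back(c_vu); nxt.push_back(first[v]);
    first[v] = (int)head.size() - 1;
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int a = first[u]; a != -1; a = nxt[a]) {
        int v = head[a];
        if (cap[a] > EPS && level[v] < 0) {
          level[v] = level[u] + 1;
          q.push(v);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double pushed) {
    if (u == t) return pushed;
    for (int& a = iter[u]; a != -1; a = nxt[a]) {
      int v = head[a];
      if (cap[a] > EPS && level[v] == level[u] + 1) {
        double got = dfs(v, t, std::min(pushed, cap[a]));
        if (got > EPS) {
          cap[a] -= got;
          cap[a ^ 1] += got;
          return got;
        }
      }
    }
    level[u] = -1;
    return 0;
  }

  void run(int s, int t) {
    while (bfs(s, t)) {
      for (int v = 0; v < n; ++v) iter[v] = first[v];
      while (true) {
        double got = dfs(s, t, std::numeric_limits<double>::infinity());
        if (got <= EPS) break;
        flow += got;
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".grid_mincut")]]
List grid_mincut(int n, IntegerMatrix edges, NumericVector cap_fwd,
                 NumericVector cap_rev, NumericVector cap_src,
                 NumericVector cap_snk) {
  int s = n, t = n + 1;
  Dinic din(n + 2);
  for (int v = 0; v < n; ++v) {
    if (cap_src[v] > 0) din.add_edge(s, v, cap_src[v], 0.0);
    if (cap_snk[v] > 0) din.add_edge(v, t, cap_snk[v], 0.0);
  }
  for (int e = 0; e < edges.nrow(); ++e) {
    din.add_edge(edges(e, 0), edges(e, 1), cap_fwd[e], cap_rev[e]);
  }
  din.run(s, t);
  // source side of the min cut: residual-reachable from s
  std::vector<char> vis(n + 2, 0);
  std::queue<int> q;
  vis[s] = 1; q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int a = din.first[u]; a != -1; a = din.nxt[a]) {
      if (din.cap[a] > EPS && !vis[din.head[a]]) {
        vis[din.head[a]] = 1;
        q.push(din.head[a]);
      }
    }
  }
  LogicalVector source_side(n);
  for (int v = 0; v < n; ++v) source_side[v] = vis[v] != 0;
  return List::create(_["flow"] = din.flow, _["source_side"] = source_side);
}
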