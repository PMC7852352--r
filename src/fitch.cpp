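#include <Rcpp.h>
using namespace Rcpp;

// Fitch small-parsimony machinery on unrooted binary trees.
//
// Trees are edge lists over node ids 1..n_nodes with tips 1..n_tips.
// Character states are bitmasks over {A=1, C=2, G=4, T=8}; missing (N) is
// the full set 15 and never forces a change. Scoring roots the tree on the
// pendant edge of tip 1, which keeps every internal node binary so the
// classic intersect-else-union recursion is exact.

static int score_tree(const std::vector<int>& from, const std::vector<int>& to,
                      const IntegerMatrix& tip_states, int n_tips) {
  int n_edges = from.size();
  int n_nodes = n_tips + (n_edges - n_tips) + 1; // unrooted binary: edges = 2*tips-3
  int n_col = tip_states.ncol();

  std::vector<std::vector<int> > adj(n_nodes + 1);
  for (int e = 0; e < n_edges; ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }

  // iterative post-order DFS rooted at tip 1's neighbour, tip 1 as parent
  int top = adj[1][0];
  std::vector<int> order, stack, parent(n_nodes + 1, 0);
  stack.push_back(top);
  parent[top] = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < adj[v].size(); ++k) {
      int w = adj[v][k];
      if (w != parent[v]) { parent[w] = v; stack.push_back(w); }
    }
  }

  std::vector<int> state((n_nodes + 1) * n_col, 0);
  std::vector<char> filled(n_nodes + 1, 0);
  int score = 0;
  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int v = order[i];
    if (v <= n_tips) {
      for (int c = 0; c < n_col; ++c) state[v * n_col + c] = tip_states(v - 1, c);
    }
    int p = parent[v];
    if (p == 1) continue; // combine with tip 1 at the very end
    if (!filled[p]) {
      for (int c = 0; c < n_col; ++c) state[p * n_col + c] = state[v * n_col + c];
      filled[p] = 1;
    } else {
      for (int c = 0; c < n_col; ++c) {
        int inter = state[p * n_col + c] & state[v * n_col + c];
        if (inter == 0) {
          ++score;
          state[p * n_col + c] |= state[v * n_col + c];
        } else {
          state[p * n_col + c] = inter;
        }
      }
    }
  }
  for (int c = 0; c < n_col; ++c) {
    if ((state[top * n_col + c] & tip_states(0, c)) == 0) ++score;
  }
  return score;
}

// [[Rcpp::export]]
int fitch_score_edges(IntegerMatrix edges, IntegerMatrix tip_states, int n_tips) {
  int n_edges = edges.nrow();
  std::vector<int> from(n_edges), to(n_edges);
  for (int e = 0; e < n_edges; ++e) { from[e] = edges(e, 0); to[e] = edges(e, 1); }
  return score_tree(from, to, tip_states, n_tips);
}

// Exhaustive maximum parsimony by stepwise topology enumeration: starting
// from the unique 3-tip tree, each further tip is attached to every edge in
// turn. Deterministic enumeration order; ties keep the first-found tree.
struct Enumerator {
  const IntegerMatrix& tip_states;
  int n_tips;
  std::vector<int> from, to;
  int next_internal;
  int best_score;
  std::vector<int> best_from, best_to;
  long n_trees;

  Enumerator(const IntegerMatrix& ts, int nt)
    : tip_states(ts), n_tips(nt), best_score(INT_MAX), n_trees(0) {}

  void run() {
    from.assign(3, n_tips + 1);
    to.resize(3);
    to[0] = 1; to[1] = 2; to[2] = 3;
    next_internal = n_tips + 2;
    recurse(4);
  }

  void recurse(int tip) {
    if (tip > n_tips) {
      ++n_trees;
      int s = score_tree(from, to, tip_states, n_tips);
      if (s < best_score) { best_score = s; best_from = from; best_to = to; }
      return;
    }
    int n_edges = from.size();
    for (int e = 0; e < n_edges; ++e) {
      int u = from[e], v = to[e], mid = next_internal;
      // subdivide edge e with `mid`, hang `tip` from it
      to[e] = mid;
      from.push_back(mid); to.push_back(v);
      from.push_back(mid); to.push_back(tip);
      ++next_internal;
      recurse(tip + 1);
      --next_internal;
      from.pop_back(); to.pop_back();
      from.pop_back(); to.pop_back();
      to[e] = v;
      (void)u;
    }
  }
};

// [[Rcpp::export]]
List exhaustive_mp(IntegerMatrix tip_states, int n_tips) {
  if (n_tips < 4) stop("need at least 4 tips for a topology search");
  Enumerator en(tip_states, n_tips);
  en.run();
  int n_edges = en.best_from.size();
  IntegerMatrix edges(n_edges, 2);
  for (int e = 0; e < n_edges; ++e) {
    edges(e, 0) = en.best_from[e];
    edges(e, 1) = en.best_to[e];
  }
  return List::create(_["edges"] = edges, _["score"] = en.best_score,
                      _["n_trees"] = (double)en.n_trees);
}
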