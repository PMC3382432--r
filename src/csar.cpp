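#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Union-find over the nodes that occur in the edge list; isolated node ids
// (never touched by an edge) do not contribute components.
static int weak_components(const std::vector<int>& from,
                           const std::vector<int>& to,
                           int n_nodes) {
  std::vector<int> parent(n_nodes, -1);
  std::vector<int> stack;
  // find with path halving
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p_) : p(p_) {}
    int find(int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  } uf(parent);
  for (size_t e = 0; e < from.size(); ++e) {
    int a = from[e], b = to[e];
    if (parent[a] == -1) parent[a] = a;
    if (parent[b] == -1) parent[b] = b;
    int ra = uf.find(a), rb = uf.find(b);
    if (ra != rb) parent[ra] = rb;
  }
  int ncomp = 0;
  for (int v = 0; v < n_nodes; ++v)
    if (parent[v] != -1 && uf.find(v) == v) ++ncomp;
  return ncomp;
}

// [[Rcpp::export]]
int cpp_weak_components(IntegerVector from, IntegerVector to, int n_nodes) {
  std::vector<int> f(from.size()), t(to.size());
  for (int i = 0; i < from.size(); ++i) { f[i] = from[i] - 1; t[i] = to[i] - 1; }
  return weak_components(f, t, n_nodes);
}

// Degree-preserving randomization of a simple directed graph by edge
// switching: pick edges (a,b),(c,d) uniformly, propose (a,d),(c,b); reject
// proposals that would create a self-loop or a parallel edge.  Batches of K
// accepted switches run between weak-connectivity checks; a failed check
// (component count above max_components) rolls the batch back and halves K,
// a success commits it and doubles K.  Edge slots keep their origin (and
// therefore their sign, held R-side): a switch only exchanges the targets of
// the two slots.  Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_randomize_graph(IntegerVector from, IntegerVector to, int n_nodes,
                         double switches_per_edge, int k_init,
                         int max_components) {
  int E = from.size();
  if (E < 2) stop("need at least 2 edges to switch");
  std::vector<int> f(E), t(E);
  std::unordered_set<long long> keys;
  keys.reserve(E * 2);
  const long long NN = (long long)n_nodes;
  for (int i = 0; i < E; ++i) {
    f[i] = from[i] - 1;
    t[i] = to[i] - 1;
    if (f[i] == t[i]) stop("input graph has a self-loop");
    if (!keys.insert((long long)f[i] * NN + t[i]).second)
      stop("input graph has a parallel edge");
  }
  long long target = (long long)std::ceil(switches_per_edge * E);
  long long committed = 0, accepted_in_batch = 0;
  long long rejected = 0, checks = 0, failures = 0, proposals = 0;
  const long long max_proposals = 2000LL * target + 1000000LL;
  int K = std::max(1, k_init);
  std::vector<int> t_good = t;
  bool exhausted = false;

  while (committed < target) {
    accepted_in_batch = 0;
    while (accepted_in_batch < K && committed + accepted_in_batch < target) {
      if (++proposals > max_proposals) { exhausted = true; break; }
      int i = (int)(unif_rand() * E);
      int j = (int)(unif_rand() * E);
      if (i >= E) i = E - 1;
      if (j >= E) j = E - 1;
      if (i == j) { ++rejected; continue; }
      int a = f[i], b = t[i], c = f[j], d = t[j];
      if (a == d || c == b) { ++rejected; continue; } // self-loops
      long long kad = (long long)a * NN + d, kcb = (long long)c * NN + b;
      // b==d or a==c make (a,d) or (c,b) coincide with a current edge
      if (keys.count(kad) || keys.count(kcb)) { ++rejected; continue; }
      keys.erase((long long)a * NN + b);
      keys.erase((long long)c * NN + d);
      keys.insert(kad);
      keys.insert(kcb);
      t[i] = d;
      t[j] = b;
      ++accepted_in_batch;
    }
    ++checks;
    if (weak_components(f, t, n_nodes) <= max_components) {
      t_good = t;
      committed += accepted_in_batch;
      K = std::min(K * 2, E * 4);
    } else {
      ++failures;
      rejected += accepted_in_batch;
      t = t_good;
      keys.clear();
      for (int i = 0; i < E; ++i) keys.insert((long long)f[i] * NN + t[i]);
    }
    if (exhausted) break;
  }

  IntegerVector to_out(E);
  for (int i = 0; i < E; ++i) to_out[i] = t_good[i] + 1;
  return List::create(_["to"] = to_out,
                      _["accepted"] = (double)committed,
                      _["rejected"] = (double)rejected,
                      _["checks"] = (double)checks,
                      _["failures"] = (double)failures,
                      _["exhausted"] = exhausted);
}

// Per-set coherence summaries from a cached absolute-correlation matrix.
// sets: list of 1-based row/column index vectors (each length >= 2).
// Returns, per set, the mean |cor| over unordered pairs (mu), the count of
// pairs with |cor| strictly above the cutoff (c_pairs), and the number of
// members participating in at least one supra-cutoff pair (n_c).
// [[Rcpp::export]]
List cpp_score_sets(NumericMatrix C, List sets, double cutoff) {
  int R = sets.size();
  NumericVector mu(R);
  IntegerVector c_pairs(R), n_out(R), n_c(R);
  for (int r = 0; r < R; ++r) {
    IntegerVector idx = sets[r];
    int n = idx.size();
    if (n < 2) stop("each set needs at least 2 members");
    std::vector<char> coh(n, 0);
    double s = 0.0;
    int cp = 0;
    for (int i = 0; i < n - 1; ++i) {
      int ii = idx[i] - 1;
      for (int j = i + 1; j < n; ++j) {
        double v = C(ii, idx[j] - 1);
        s += v;
        if (v > cutoff) {
          ++cp;
          coh[i] = 1;
          coh[j] = 1;
        }
      }
    }
    double npair = (double)n * (n - 1) / 2.0;
    mu[r] = s / npair;
    c_pairs[r] = cp;
    n_out[r] = n;
    int nc = 0;
    for (int i = 0; i < n; ++i) nc += coh[i];
    n_c[r] = nc;
  }
  return List::create(_["mu"] = mu, _["c_pairs"] = c_pairs, _["n"] = n_out,
                      _["n_c"] = n_c);
}
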