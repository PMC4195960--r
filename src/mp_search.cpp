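// Maximum-parsimony search over binary (presence/absence) characters.
//
// Taxa are rows of a 0/1 matrix; row 0 is by convention the designated
// ancestral haplotype and is treated as an ordinary taxon during the
// unrooted search (rooting happens on the R side).  Internal nodes are
// numbered T, T+1, ... as taxa are joined.  Trees are unrooted and binary
// during the search; zero-length edges are collapsed later in R.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct FitchEngine {
  int T, S;                       // taxa, site patterns
  std::vector<uint8_t> X;         // T x S taxon states (0/1)
  std::vector<int> w;             // pattern weights
  std::vector<std::vector<int>> adj;
  std::vector<uint8_t> sets;      // per-node bitsets (1={0}, 2={1}, 3={0,1})
  int nNodes;

  FitchEngine(const IntegerMatrix& M, const IntegerVector& weights) {
    T = M.nrow();
    S = M.ncol();
    X.resize((size_t)T * S);
    for (int t = 0; t < T; ++t)
      for (int s = 0; s < S; ++s)
        X[(size_t)t * S + s] = (uint8_t)M(t, s);
    w.assign(weights.begin(), weights.end());
    nNodes = 2 * T;               // generous upper bound
    adj.assign(nNodes, {});
    sets.assign((size_t)nNodes * S, 0);
  }

  void buildAdj(const std::vector<int>& ea, const std::vector<int>& eb) {
    int hi = 0;
    for (size_t i = 0; i < ea.size(); ++i)
      hi = std::max(hi, std::max(ea[i], eb[i]));
    for (int v = 0; v <= hi; ++v) adj[v].clear();
    for (size_t i = 0; i < ea.size(); ++i) {
      adj[ea[i]].push_back(eb[i]);
      adj[eb[i]].push_back(ea[i]);
    }
  }

  // post-order Fitch from node (parent given); accumulates cost
  void down(int node, int parent, int& cost) {
    uint8_t* my = &sets[(size_t)node * S];
    if (node < T) {
      const uint8_t* x = &X[(size_t)node * S];
      for (int s = 0; s < S; ++s) my[s] = (uint8_t)(1u << x[s]);
      return;
    }
    bool first = true;
    for (int nb : adj[node]) {
      if (nb == parent) continue;
      down(nb, node, cost);
      const uint8_t* ch = &sets[(size_t)nb * S];
      if (first) {
        std::copy(ch, ch + S, my);
        first = false;
      } else {
        for (int s = 0; s < S; ++s) {
          uint8_t inter = my[s] & ch[s];
          if (inter) my[s] = inter;
          else { my[s] = my[s] | ch[s]; cost += w[s]; }
        }
      }
    }
  }

  // parsimony length of an unrooted tree, rooted for traversal at taxon 0
  int length(const std::vector<int>& ea, const std::vector<int>& eb) {
    buildAdj(ea, eb);
    if (adj[0].empty()) return 0;
    int v = adj[0][0];
    int cost = 0;
    down(v, 0, cost);
    const uint8_t* sv = &sets[(size_t)v * S];
    const uint8_t* x0 = &X[0];
    for (int s = 0; s < S; ++s)
      if (!(sv[s] & (1u << x0[s]))) cost += w[s];
    return cost;
  }
};

struct BnB {
  FitchEngine eng;
  std::vector<int> order;         // taxa in addition order; order[0..2] start
  std::vector<int> ea, eb;
  int best;
  long long nOpt;
  int maxStore;
  std::vector<std::pair<std::vector<int>, std::vector<int>>> opts;

  BnB(const IntegerMatrix& M, const IntegerVector& w, int maxStore_)
    : eng(M, w), maxStore(maxStore_) {
    int T = eng.T;
    // addition order: taxon 0 first, then by decreasing weighted distance
    // to taxon 0 (ties by index) so divergent taxa constrain early
    std::vector<std::pair<int,int>> d;
    for (int t = 1; t < T; ++t) {
      int dist = 0;
      for (int s = 0; s < eng.S; ++s)
        if (eng.X[(size_t)t * eng.S + s] != eng.X[s]) dist += eng.w[s];
      d.push_back({-dist, t});
    }
    std::sort(d.begin(), d.end());
    order.push_back(0);
    for (auto& p : d) order.push_back(p.second);
    best = INT_MAX;
    nOpt = 0;
  }

  void startTree() {
    int T = eng.T;
    ea = {order[0], order[1], order[2]};
    eb = {T, T, T};
  }

  void greedyFill() {
    startTree();
    int T = eng.T;
    for (int k = 3; k < T; ++k) {
      int taxon = order[k], newInt = T + k - 2;
      int bestLen = INT_MAX, bestEdge = -1;
      int nE = (int)ea.size();
      for (int i = 0; i < nE; ++i) {
        int u = ea[i], v = eb[i];
        ea[i] = u; eb[i] = newInt;
        ea.push_back(newInt); eb.push_back(v);
        ea.push_back(newInt); eb.push_back(taxon);
        int len = eng.length(ea, eb);
        if (len < bestLen) { bestLen = len; bestEdge = i; }
        ea.pop_back(); eb.pop_back();
        ea.pop_back(); eb.pop_back();
        ea[i] = u; eb[i] = v;
      }
      int u = ea[bestEdge], v = eb[bestEdge];
      ea[bestEdge] = u; eb[bestEdge] = newInt;
      ea.push_back(newInt); eb.push_back(v);
      ea.push_back(newInt); eb.push_back(taxon);
    }
  }

  // nearest-neighbour interchange until no strict improvement
  int nni() {
    int T = eng.T;
    int len = eng.length(ea, eb);
    bool improved = true;
    while (improved) {
      improved = false;
      int nE = (int)ea.size();
      for (int i = 0; i < nE && !improved; ++i) {
        int u = ea[i], v = eb[i];
        if (u < T || v < T) continue;        // internal edges only
        // neighbours of u other than v, and of v other than u
        std::vector<int> un, vn;             // edge indices
        for (int j = 0; j < nE; ++j) {
          if (j == i) continue;
          if (ea[j] == u || eb[j] == u) un.push_back(j);
          if (ea[j] == v || eb[j] == v) vn.push_back(j);
        }
        for (size_t a = 0; a < un.size() && !improved; ++a)
          for (size_t b = 0; b < vn.size() && !improved; ++b) {
            if (a == 1 && b == 1) continue;  // second swap duplicates first
            int j1 = un[a], j2 = vn[b];
            // detach subtrees: swap the far endpoints
            int far1 = (ea[j1] == u) ? 1 : 0;  // which side of j1 is u
            int far2 = (ea[j2] == v) ? 1 : 0;
            int s1 = far1 ? eb[j1] : ea[j1];
            int s2 = far2 ? eb[j2] : ea[j2];
            // reconnect: s1 to v, s2 to u
            if (far1) eb[j1] = s2; else ea[j1] = s2;
            if (far2) eb[j2] = s1; else ea[j2] = s1;
            // j1 must attach to u still; fix endpoints: j1=(u,s2), j2=(v,s1)
            // (the assignment above replaced the subtree endpoints)
            int l2 = eng.length(ea, eb);
            if (l2 < len) { len = l2; improved = true; }
            else {
              if (far1) eb[j1] = s1; else ea[j1] = s1;
              if (far2) eb[j2] = s2; else ea[j2] = s2;
            }
          }
      }
    }
    return len;
  }

  long long evals = 0, maxEval = -1;
  bool aborted = false;

  void search(int k) {
    if (aborted) return;
    if (maxEval > 0 && ++evals > maxEval) { aborted = true; return; }
    int T = eng.T;
    if (k == T) {
      int len = eng.length(ea, eb);
      if (len < best) { best = len; nOpt = 0; opts.clear(); }
      if (len == best) {
        ++nOpt;
        if ((int)opts.size() < maxStore) opts.push_back({ea, eb});
      }
      return;
    }
    int taxon = order[k], newInt = T + k - 2;
    int nE = (int)ea.size();
    for (int i = 0; i < nE; ++i) {
      int u = ea[i], v = eb[i];
      ea[i] = u; eb[i] = newInt;
      ea.push_back(newInt); eb.push_back(v);
      ea.push_back(newInt); eb.push_back(taxon);
      if (eng.length(ea, eb) <= best) search(k + 1);
      ea.pop_back(); eb.pop_back();
      ea.pop_back(); eb.pop_back();
      ea[i] = u; eb[i] = v;
    }
  }
};

IntegerMatrix edgesToMatrix(const std::vector<int>& ea,
                            const std::vector<int>& eb) {
  IntegerMatrix E((int)ea.size(), 2);
  for (size_t i = 0; i < ea.size(); ++i) {
    E(i, 0) = ea[i];
    E(i, 1) = eb[i];
  }
  return E;
}

} // namespace

// [[Rcpp::export(name = ".cpp_mp_exact")]]
List cpp_mp_exact(IntegerMatrix X, IntegerVector weights, int maxStore,
                  double maxEval) {
  int T = X.nrow();
  if (T < 4) stop("exact search needs >= 4 taxa (smaller handled in R)");
  BnB bnb(X, weights, maxStore);
  // greedy bound first
  bnb.greedyFill();
  bnb.best = bnb.nni();
  bnb.maxEval = (long long)maxEval;
  bnb.startTree();
  bnb.search(3);
  List trees(bnb.opts.size());
  for (size_t i = 0; i < bnb.opts.size(); ++i)
    trees[i] = edgesToMatrix(bnb.opts[i].first, bnb.opts[i].second);
  return List::create(_["length"] = bnb.best,
                      _["trees"] = trees,
                      _["n_optimal"] = (double)bnb.nOpt,
                      _["aborted"] = bnb.aborted);
}

// [[Rcpp::export(name = ".cpp_mp_greedy")]]
List cpp_mp_greedy(IntegerMatrix X, IntegerVector weights) {
  int T = X.nrow();
  if (T < 4) stop("greedy search needs >= 4 taxa (smaller handled in R)");
  BnB bnb(X, weights, 1);
  bnb.greedyFill();
  int len = bnb.nni();
  return List::create(_["length"] = len,
                      _["tree"] = edgesToMatrix(bnb.ea, bnb.eb));
}

// [[Rcpp::export(name = ".cpp_fitch_length")]]
int cpp_fitch_length(IntegerMatrix edges, IntegerMatrix X,
                     IntegerVector weights) {
  FitchEngine eng(X, weights);
  std::vector<int> ea(edges.nrow()), eb(edges.nrow());
  for (int i = 0; i < edges.nrow(); ++i) { ea[i] = edges(i,0); eb[i] = edges(i,1); }
  return eng.length(ea, eb);
}
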