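// Simulated-annealing maximisation of bipartite (Barber) modularity
//
//   M = (1/F) * sum_{i,j} [ a_ij - k_i d_j / F ] * delta(g_i, g_j)
//
// over insect i, host j, with k/d the guild degrees and F the total number
// of interactions.  Moves: single-node reassignment (to an existing or a
// fresh module), module merge, module split; Metropolis acceptance on dM.
// Degree-zero nodes are excluded here and placed in singleton modules by
// the R wrapper (they cannot change M).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Bip {
  int n, m;                    // insects, hosts
  double F;
  std::vector<std::vector<int>> nbr;  // per node (0..n+m-1), neighbours
  std::vector<double> w;       // guild degree of each node (k_i or d_j)
};

// modularity of an assignment, from scratch
double full_M(const Bip& B, const std::vector<int>& g) {
  int N = B.n + B.m;
  std::vector<double> K(N, 0.0), D(N, 0.0);  // per-module degree sums
  double within = 0.0;
  for (int i = 0; i < B.n; ++i) {
    K[g[i]] += B.w[i];
    for (int j : B.nbr[i]) if (g[j] == g[i]) within += 1.0;
  }
  for (int j = B.n; j < N; ++j) D[g[j]] += B.w[j];
  double pen = 0.0;
  for (int c = 0; c < N; ++c) pen += K[c] * D[c];
  return within / B.F - pen / (B.F * B.F);
}

struct State {
  const Bip* B;
  std::vector<int> g;                 // module of each node
  std::vector<double> K, D;           // per-module insect / host degree sums
  std::vector<int> size;              // members per module
  std::vector<int> active;            // ids of non-empty modules
  std::vector<int> apos;              // position of module in `active` (-1 if empty)
  double M;

  void init(const Bip& bip, const std::vector<int>& g0) {
    B = &bip;
    int N = bip.n + bip.m;
    g = g0;
    K.assign(N, 0.0); D.assign(N, 0.0); size.assign(N, 0);
    apos.assign(N, -1); active.clear();
    for (int v = 0; v < N; ++v) {
      int c = g[v];
      if (size[c]++ == 0) { apos[c] = active.size(); active.push_back(c); }
      if (v < bip.n) K[c] += bip.w[v]; else D[c] += bip.w[v];
    }
    M = full_M(bip, g);
  }

  int links_to(int v, int c) const {
    int e = 0;
    for (int u : B->nbr[v]) if (g[u] == c) ++e;
    return e;
  }

  // dM for moving node v from its module to module c
  double delta_move(int v, int c) const {
    int s = g[v];
    if (s == c) return 0.0;
    double F = B->F;
    int es = links_to(v, s), ec = links_to(v, c);
    double other_s, other_c;       // opposite-guild degree sums
    if (v < B->n) { other_s = D[s]; other_c = D[c]; }
    else          { other_s = K[s]; other_c = K[c]; }
    return (ec - es) / F - B->w[v] * (other_c - other_s) / (F * F);
  }

  void apply_move(int v, int c) {
    int s = g[v];
    M += delta_move(v, c);
    g[v] = c;
    if (v < B->n) { K[s] -= B->w[v]; K[c] += B->w[v]; }
    else          { D[s] -= B->w[v]; D[c] += B->w[v]; }
    if (size[c]++ == 0) { apos[c] = active.size(); active.push_back(c); }
    if (--size[s] == 0) {
      int p = apos[s], last = active.back();
      active[p] = last; apos[last] = p;
      active.pop_back(); apos[s] = -1;
    }
  }

  // dM for merging modules s and t (edges between them minus penalty)
  double delta_merge(int s, int t) const {
    double e = 0.0;
    for (int i = 0; i < B->n; ++i)
      if (g[i] == s || g[i] == t) {
        int want = (g[i] == s) ? t : s;
        for (int j : B->nbr[i]) if (g[j] == want) e += 1.0;
      }
    double F = B->F;
    return e / F - (K[s] * D[t] + K[t] * D[s]) / (F * F);
  }

  void apply_merge(int s, int t) {   // t absorbed into s
    M += delta_merge(s, t);
    int N = B->n + B->m;
    for (int v = 0; v < N; ++v) if (g[v] == t) {
      g[v] = s; ++size[s];
      if (v < B->n) { K[t] -= B->w[v]; K[s] += B->w[v]; }
      else          { D[t] -= B->w[v]; D[s] += B->w[v]; }
    }
    size[t] = 0;
    int p = apos[t], last = active.back();
    active[p] = last; apos[last] = p;
    active.pop_back(); apos[t] = -1;
  }

  int free_module() const {
    for (int c = 0; c < (int)size.size(); ++c) if (size[c] == 0) return c;
    return -1;
  }
};

}  // namespace

namespace {

// greedy hill-climb: move nodes to their best module until no move improves
void refine(State& st, const std::vector<int>& movable) {
  const Bip& B = *st.B;
  bool improved = true;
  int guard = 0;
  while (improved && ++guard < 200) {
    improved = false;
    for (int v : movable) {
      int best_c = st.g[v];
      double best_d = 0.0;
      for (size_t a = 0; a < st.active.size(); ++a) {
        int c = st.active[a];
        if (c == st.g[v]) continue;
        double d = st.delta_move(v, c);
        if (d > best_d + 1e-13) { best_d = d; best_c = c; }
      }
      if (st.size[st.g[v]] > 1) {   // also consider a fresh singleton
        int c = st.free_module();
        if (c >= 0) {
          double d = st.delta_move(v, c);
          if (d > best_d + 1e-13) { best_d = d; best_c = c; }
        }
      }
      if (best_c != st.g[v]) { st.apply_move(v, best_c); improved = true; }
    }
    // merge any module pair whose union raises M
    bool merged = true;
    while (merged) {
      merged = false;
      for (size_t x = 0; x < st.active.size() && !merged; ++x)
        for (size_t y = x + 1; y < st.active.size() && !merged; ++y) {
          int s = st.active[x], t = st.active[y];
          if (st.delta_merge(s, t) > 1e-13) {
            st.apply_merge(s, t);
            merged = true; improved = true;
          }
        }
    }
  }
  st.M = full_M(B, st.g);
}

}  // namespace

// One annealing chain.  Returns list(assignment, M).
// [[Rcpp::export(name = ".anneal_chain")]]
List anneal_chain(IntegerMatrix adj, IntegerVector init,
                  double t0, double cooling, int steps_per_temp,
                  int stall_limit, int seed) {
  Bip B;
  B.n = adj.nrow(); B.m = adj.ncol();
  int N = B.n + B.m;
  B.nbr.assign(N, {});
  B.w.assign(N, 0.0);
  double F = 0.0;
  for (int i = 0; i < B.n; ++i)
    for (int j = 0; j < B.m; ++j)
      if (adj(i, j) == 1) {
        B.nbr[i].push_back(B.n + j);
        B.nbr[B.n + j].push_back(i);
        F += 1.0;
      }
  if (F <= 0.0) stop("network has no interactions");
  B.F = F;
  for (int v = 0; v < N; ++v) B.w[v] = B.nbr[v].size();

  std::vector<int> movable;
  for (int v = 0; v < N; ++v) if (!B.nbr[v].empty()) movable.push_back(v);

  State st;
  st.init(B, as<std::vector<int>>(init));

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  auto pick = [&](int k) { return (int)(rng() % (uint32_t)k); };

  // calibrate T0 so ~half of the early downhill moves would be accepted
  double T = t0;
  if (T <= 0.0) {
    std::vector<double> drops;
    for (int it = 0; it < 256; ++it) {
      int v = movable[pick(movable.size())];
      int c = st.active[pick(st.active.size())];
      double d = st.delta_move(v, c);
      if (d < 0) drops.push_back(-d);
    }
    if (drops.empty()) T = 1.0 / F;
    else {
      std::nth_element(drops.begin(), drops.begin() + drops.size() / 2, drops.end());
      T = drops[drops.size() / 2] / std::log(2.0);
    }
    if (T <= 0.0) T = 1.0 / F;
  }

  std::vector<int> best_g = st.g;
  double best_M = st.M;
  int stall = 0;
  double Tmin = T * 1e-8;

  while (stall < stall_limit && T > Tmin) {
    for (int step = 0; step < steps_per_temp; ++step) {
      double u = U(rng);
      if (u < 0.90 || st.active.size() < 2) {
        // single-node move to a random module (possibly a fresh one)
        int v = movable[pick(movable.size())];
        int c;
        if (st.size[st.g[v]] > 1 && U(rng) < 1.0 / (st.active.size() + 1.0)) {
          c = st.free_module();
          if (c < 0) continue;
        } else {
          c = st.active[pick(st.active.size())];
        }
        if (c == st.g[v]) continue;
        double d = st.delta_move(v, c);
        if (d >= 0 || U(rng) < std::exp(d / T)) st.apply_move(v, c);
      } else if (u < 0.95) {
        // merge two random modules
        int s = st.active[pick(st.active.size())];
        int t = st.active[pick(st.active.size())];
        if (s == t) continue;
        double d = st.delta_merge(s, t);
        if (d >= 0 || U(rng) < std::exp(d / T)) st.apply_merge(s, t);
      } else {
        // split a random module by random bisection
        int s = st.active[pick(st.active.size())];
        if (st.size[s] < 2) continue;
        int c = st.free_module();
        if (c < 0) continue;
        std::vector<int> mem;
        for (int v = 0; v < N; ++v) if (st.g[v] == s) mem.push_back(v);
        std::vector<int> half;
        for (int v : mem) if (U(rng) < 0.5) half.push_back(v);
        if (half.empty() || half.size() == mem.size()) continue;
        double M_before = st.M;
        std::vector<int> g_before = st.g;
        for (int v : half) st.apply_move(v, c);
        double d = st.M - M_before;
        if (!(d >= 0 || U(rng) < std::exp(d / T))) {
          for (int v : half) st.apply_move(v, s);  // undo
          st.g = g_before;
        }
      }
      if (st.M > best_M + 1e-12) { best_M = st.M; best_g = st.g; stall = -1; }
    }
    // guard against numeric drift of the incremental M
    st.M = full_M(B, st.g);
    ++stall;
    T *= cooling;
  }

  // polish the best state found by the chain with a greedy local search
  st.init(B, best_g);
  refine(st, movable);

  return List::create(_["assignment"] = wrap(st.g),
                      _["M"] = full_M(B, st.g));
}

// Barber bipartite modularity of a given assignment (fast path for nulls).
// [[Rcpp::export(name = ".bip_modularity_cpp")]]
double bip_modularity_cpp(IntegerMatrix adj, IntegerVector gi, IntegerVector gh) {
  int n = adj.nrow(), m = adj.ncol();
  Bip B; B.n = n; B.m = m;
  B.nbr.assign(n + m, {});
  double F = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (adj(i, j) == 1) { B.nbr[i].push_back(n + j); F += 1.0; }
  if (F <= 0.0) stop("network has no interactions");
  B.F = F;
  B.w.assign(n + m, 0.0);
  for (int i = 0; i < n; ++i) B.w[i] = B.nbr[i].size();
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) if (adj(i, j) == 1) B.w[n + j] += 1.0;
  std::vector<int> g(n + m);
  for (int i = 0; i < n; ++i) g[i] = gi[i];
  for (int j = 0; j < m; ++j) g[n + j] = gh[j];
  return full_M(B, g);
}
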