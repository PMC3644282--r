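// Core machinery for consensus Bayesian-network structure learning on
// discrete (trinary) data: BDeu family scores, random-restart greedy hill
// climbing over add/delete/reverse moves, and the R-run undirected edge
// frequency ("dependency likelihood") matrix.
//
// Determinism contract: given (data, config, seed) every function here is
// bit-reproducible. Randomness comes from a private splitmix64/xoshiro
// generator, never from R's RNG, so permutation subsets drawn in R cannot
// disturb search trajectories.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// PRNG: splitmix64 for seeding / mixing, xoshiro256** for the stream.

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Fold (base seed, stream index) into one 64-bit seed.
static inline uint64_t mix_seed(uint64_t base, uint64_t idx) {
  uint64_t s = base;
  uint64_t a = splitmix64_next(s);
  s ^= idx * 0x9E3779B97F4A7C15ULL;
  uint64_t b = splitmix64_next(s);
  return a ^ (b + 0x632BE59BD9B4E019ULL);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// ---------------------------------------------------------------------------
// BDeu scorer with per-alpha lgamma tables and a per-dataset family cache.

// Open-addressing cache of family scores keyed by (child, parent bitmask);
// the same families recur constantly across the R runs of one consensus.
class FamilyCache {
public:
  FamilyCache() { resize(1 << 16); }
  bool get(uint64_t key, double &out) const {
    size_t i = slot(key);
    while (keys_[i] != EMPTY) {
      if (keys_[i] == key) { out = vals_[i]; return true; }
      i = (i + 1) & mask_;
    }
    return false;
  }
  void put(uint64_t key, double val) {
    if (2 * (used_ + 1) > keys_.size()) grow();
    size_t i = slot(key);
    while (keys_[i] != EMPTY) {
      if (keys_[i] == key) { vals_[i] = val; return; }
      i = (i + 1) & mask_;
    }
    keys_[i] = key; vals_[i] = val; ++used_;
  }

private:
  static constexpr uint64_t EMPTY = ~0ULL;
  std::vector<uint64_t> keys_;
  std::vector<double> vals_;
  size_t mask_ = 0, used_ = 0;
  size_t slot(uint64_t key) const {
    uint64_t h = key * 0x9E3779B97F4A7C15ULL;
    return (size_t)(h >> 32) & mask_;
  }
  void resize(size_t n) {
    keys_.assign(n, EMPTY);
    vals_.assign(n, 0.0);
    mask_ = n - 1; used_ = 0;
  }
  void grow() {
    std::vector<uint64_t> ok;
    std::vector<double> ov;
    ok.swap(keys_); ov.swap(vals_);
    resize(2 * ok.size());
    for (size_t i = 0; i < ok.size(); ++i)
      if (ok[i] != EMPTY) put(ok[i], ov[i]);
  }
};

class Scorer {
public:
  Scorer(const IntegerMatrix &data, const IntegerVector &arity, double ess)
      : data_(data), arity_(arity), ess_(ess), n_(data.nrow()),
        N_(data.ncol()) {
    cache_enabled_ = (n_ <= 32);
  }

  int nvars() const { return n_; }
  int nsamples() const { return N_; }

  // log marginal likelihood of one family (child given parent set)
  double family(int child, const std::vector<int> &parents) {
    if (cache_enabled_) {
      uint64_t mask = 0;
      for (int p : parents) mask |= (1ULL << p);
      return family_key(child, mask, &parents);
    }
    return compute(child, parents);
  }

  // family score for (base parent set) +/- one parent, avoiding the
  // modified-vector build on cache hits
  double family_mod(int child, const std::vector<int> &base, int mod,
                    bool remove) {
    if (cache_enabled_) {
      uint64_t mask = 0;
      for (int p : base) mask |= (1ULL << p);
      if (remove) mask &= ~(1ULL << mod); else mask |= (1ULL << mod);
      return family_key(child, mask, nullptr);
    }
    std::vector<int> ps(base);
    if (remove) ps.erase(std::lower_bound(ps.begin(), ps.end(), mod));
    else ps.insert(std::upper_bound(ps.begin(), ps.end(), mod), mod);
    return compute(child, ps);
  }

private:
  IntegerMatrix data_;
  IntegerVector arity_;
  double ess_;
  int n_, N_;
  bool cache_enabled_;
  FamilyCache cache_;

  double family_key(int child, uint64_t mask, const std::vector<int> *ps) {
    uint64_t key = ((uint64_t)child << 32) | mask;
    double s;
    if (cache_.get(key, s)) return s;
    std::vector<int> built;
    if (!ps) {
      while (mask) {
        built.push_back(__builtin_ctzll(mask));
        mask &= mask - 1;
      }
      ps = &built;
    }
    s = compute(child, *ps);
    cache_.put(key, s);
    return s;
  }
  // lgamma(alpha + k), k = 0..N, keyed by alpha
  std::unordered_map<double, std::vector<double>> lg_;

  const std::vector<double> &lgtab(double alpha) {
    auto it = lg_.find(alpha);
    if (it != lg_.end()) return it->second;
    std::vector<double> v(N_ + 1);
    for (int k = 0; k <= N_; ++k) v[k] = std::lgamma(alpha + k);
    return lg_.emplace(alpha, std::move(v)).first->second;
  }

  double compute(int child, const std::vector<int> &parents) {
    int r = arity_[child];
    long q = 1;
    for (int p : parents) q *= arity_[p];
    double a_jk = ess_ / (double)(q * r);
    double a_j = ess_ / (double)q;
    // counts over q * r cells
    std::vector<int> counts((size_t)q * r, 0);
    std::vector<long> stride(parents.size());
    long st = 1;
    for (size_t i = 0; i < parents.size(); ++i) {
      stride[i] = st;
      st *= arity_[parents[i]];
    }
    for (int s = 0; s < N_; ++s) {
      long j = 0;
      for (size_t i = 0; i < parents.size(); ++i)
        j += stride[i] * data_(parents[i], s);
      counts[(size_t)j * r + data_(child, s)]++;
    }
    const std::vector<double> &ljk = lgtab(a_jk);
    const std::vector<double> &lj = lgtab(a_j);
    double score = 0.0;
    for (long j = 0; j < q; ++j) {
      int nj = 0;
      bool seen = false;
      for (int k = 0; k < r; ++k) {
        int c = counts[(size_t)j * r + k];
        if (c > 0) { score += ljk[c] - ljk[0]; nj += c; seen = true; }
      }
      if (seen) score += lj[0] - lj[nj];
    }
    return score;
  }
};

// ---------------------------------------------------------------------------
// DAG utilities.

struct Dag {
  int n;
  std::vector<uint8_t> adj;               // adj[i * n + j] = 1 iff i -> j
  std::vector<std::vector<int>> parents;  // sorted parent lists
  explicit Dag(int n_) : n(n_), adj((size_t)n_ * n_, 0), parents(n_) {}

  bool has_edge(int i, int j) const { return adj[(size_t)i * n + j]; }
  void add(int i, int j) {
    adj[(size_t)i * n + j] = 1;
    auto &v = parents[j];
    v.insert(std::upper_bound(v.begin(), v.end(), i), i);
  }
  void del(int i, int j) {
    adj[(size_t)i * n + j] = 0;
    auto &v = parents[j];
    v.erase(std::lower_bound(v.begin(), v.end(), i));
  }
  // would adding i -> j create a cycle? (true if a path j ~> i exists;
  // walk ancestors of i looking for j)
  bool creates_cycle(int i, int j) const {
    if (i == j) return true;
    std::vector<char> visited(n, 0);
    std::vector<int> stack{i};
    visited[i] = 1;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      for (int p : parents[v]) {
        if (p == j) return true;
        if (!visited[p]) { visited[p] = 1; stack.push_back(p); }
      }
    }
    return false;
  }
};

// Random initial DAG: uniformly random topological order, each forward edge
// included independently with prob min(2/(n-1), 0.5), parents truncated to
// max_parents. Keeps starts sparse so run-to-run variability is informative.
static Dag random_dag(int n, int max_parents, Xoshiro &rng) {
  Dag dag(n);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);
  double p = n > 1 ? std::min(2.0 / (n - 1), 0.5) : 0.0;
  for (int b = 1; b < n; ++b) {
    int child = order[b];
    for (int a = 0; a < b; ++a) {
      if ((int)dag.parents[child].size() >= max_parents) break;
      if (rng.unif() < p) dag.add(order[a], child);
    }
  }
  return dag;
}

// ---------------------------------------------------------------------------
// Greedy hill climbing. Moves: add / delete / reverse, scanned in a fixed
// lexicographic order; strictly improving moves only (score ties, including
// "add vs don't add", resolve to the current structure); among equal best
// deltas the first move in scan order wins.

static double hill_climb(Scorer &sc, int max_parents, Xoshiro &rng, Dag &out) {
  const int n = sc.nvars();
  Dag dag = random_dag(n, max_parents, rng);
  std::vector<double> fam(n);
  double total = 0.0;
  for (int v = 0; v < n; ++v) {
    fam[v] = sc.family(v, dag.parents[v]);
    total += fam[v];
  }
  const double eps = 1e-9;
  for (;;) {
    double best = 0.0;
    int best_type = -1, best_i = -1, best_j = -1;
    double best_fj = 0.0, best_fi = 0.0;
    // adds then deletes then reversals, each (i, j) lexicographic
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (i == j || dag.has_edge(i, j)) continue;
        if ((int)dag.parents[j].size() >= max_parents) continue;
        double fj = sc.family_mod(j, dag.parents[j], i, false);
        double delta = fj - fam[j];
        if (delta > best + eps) {
          if (dag.creates_cycle(i, j)) continue;
          best = delta; best_type = 0; best_i = i; best_j = j; best_fj = fj;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (!dag.has_edge(i, j)) continue;
        double fj = sc.family_mod(j, dag.parents[j], i, true);
        double delta = fj - fam[j];
        if (delta > best + eps) {
          best = delta; best_type = 1; best_i = i; best_j = j; best_fj = fj;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (!dag.has_edge(i, j)) continue;  // reverse i->j to j->i
        if ((int)dag.parents[i].size() >= max_parents) continue;
        double fj = sc.family_mod(j, dag.parents[j], i, true);
        double fi = sc.family_mod(i, dag.parents[i], j, false);
        double delta = (fj - fam[j]) + (fi - fam[i]);
        if (delta > best + eps) {
          dag.del(i, j);
          bool cyc = dag.creates_cycle(j, i);
          dag.add(i, j);
          if (cyc) continue;
          best = delta; best_type = 2; best_i = i; best_j = j;
          best_fj = fj; best_fi = fi;
        }
      }
    }
    if (best_type < 0) break;
    if (best_type == 0) {
      dag.add(best_i, best_j);
      fam[best_j] = best_fj;
    } else if (best_type == 1) {
      dag.del(best_i, best_j);
      fam[best_j] = best_fj;
    } else {
      dag.del(best_i, best_j);
      dag.add(best_j, best_i);
      fam[best_j] = best_fj;
      fam[best_i] = best_fi;
    }
    total += best;
  }
  total = 0.0;
  for (int v = 0; v < n; ++v) total += fam[v];
  out = dag;
  return total;
}

// One search run: `restarts` hill climbs from independent random starts,
// best-scoring local optimum kept (first found wins ties).
static Dag search_run(Scorer &sc, int max_parents, int restarts,
                      uint64_t seed) {
  Dag best(sc.nvars());
  double best_score = -std::numeric_limits<double>::infinity();
  for (int r = 0; r < restarts; ++r) {
    Xoshiro rng(mix_seed(seed, (uint64_t)r));
    Dag dag(sc.nvars());
    double s = hill_climb(sc, max_parents, rng, dag);
    if (s > best_score + 1e-9) { best_score = s; best = dag; }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Exported entry points.

// [[Rcpp::export(name = ".family_score_cpp")]]
double family_score_cpp(IntegerMatrix data, IntegerVector arity, int child,
                        IntegerVector parents, double ess) {
  Scorer sc(data, arity, ess);
  std::vector<int> ps(parents.begin(), parents.end());
  std::sort(ps.begin(), ps.end());
  return sc.family(child, ps);
}

// [[Rcpp::export(name = ".search_structure_cpp")]]
IntegerMatrix search_structure_cpp(IntegerMatrix data, IntegerVector arity,
                                   int max_parents, int restarts, double ess,
                                   double seed) {
  Scorer sc(data, arity, ess);
  Dag dag = search_run(sc, max_parents, restarts, (uint64_t)seed);
  int n = data.nrow();
  IntegerMatrix adj(n, n);  // adj(i, j) = 1 iff i -> j
  for (int j = 0; j < n; ++j)
    for (int i : dag.parents[j]) adj(i, j) = 1;
  return adj;
}

// Undirected edge frequency over R independent runs (Eq. 1 machinery):
// per-run seed = mix(base_seed, run index), so disjoint run blocks never
// share search trajectories.
// [[Rcpp::export(name = ".consensus_cpp")]]
NumericMatrix consensus_cpp(IntegerMatrix data, IntegerVector arity, int R,
                            int max_parents, int restarts, double ess,
                            double base_seed, int seed_offset) {
  Scorer sc(data, arity, ess);
  int n = data.nrow();
  NumericMatrix d(n, n);
  for (int run = 0; run < R; ++run) {
    uint64_t seed = mix_seed((uint64_t)base_seed,
                             (uint64_t)(seed_offset + run + 1));
    Dag dag = search_run(sc, max_parents, restarts, seed);
    for (int j = 0; j < n; ++j)
      for (int i : dag.parents[j]) {
        d(i, j) += 1.0;
        d(j, i) += 1.0;
      }
    if ((run & 63) == 63) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) d(i, j) /= R;
  return d;
}
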