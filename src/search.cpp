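// Heuristic MR supertree search over bifurcating trees.
//
// Splits are bitmasks (up to 128 taxa) over a global taxon index supplied
// by the R layer.  A tree is its taxon mask plus the set of inner-split
// side masks; the complementary side is implicit.  All randomness comes
// from R's RNG so that set.seed() makes every search reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>

using namespace Rcpp;

struct M {
  uint64_t a, b;
};
static inline M m_zero() { return {0ull, 0ull}; }
static inline M m_and(M x, M y) { return {x.a & y.a, x.b & y.b}; }
static inline M m_or(M x, M y) { return {x.a | y.a, x.b | y.b}; }
static inline M m_diff(M x, M y) { return {x.a & ~y.a, x.b & ~y.b}; }
static inline bool m_none(M x) { return (x.a | x.b) == 0ull; }
static inline int m_pc(M x) {
  return __builtin_popcountll(x.a) + __builtin_popcountll(x.b);
}
static inline bool m_subset(M x, M y) { return m_none(m_diff(x, y)); }
static inline bool m_eq(M x, M y) { return x.a == y.a && x.b == y.b; }
static inline M m_bit(int i) {
  return i < 64 ? M{1ull << i, 0ull} : M{0ull, 1ull << (i - 64)};
}
static inline bool m_has(M x, int i) {
  return i < 64 ? ((x.a >> i) & 1ull) : ((x.b >> (i - 64)) & 1ull);
}
static inline bool m_lt(M x, M y) {
  return x.b != y.b ? x.b < y.b : x.a < y.a;
}
static inline int m_lowest(M x) {
  if (x.a) return __builtin_ctzll(x.a);
  return 64 + __builtin_ctzll(x.b);
}

struct Input {
  M taxa;
  std::vector<M> splits;   // sides, subsets of taxa
  std::vector<M> sorted;   // canonical, sorted, deduplicated split set
  int ntax;
};

struct Tree {
  M tax;
  std::vector<M> sp;       // inner split sides (subsets of tax)
};

// ---------- RNG helpers (R's RNG) ----------------------------------------

static inline int rand_index(int k) {
  int r = (int)(unif_rand() * k);
  return r >= k ? k - 1 : r;
}

template <typename T>
static void shuffle_vec(std::vector<T>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rand_index(i + 1);
    std::swap(v[i], v[j]);
  }
}

// ---------- split compatibility -------------------------------------------

// incompatibility of input split g (side within its tree) and supertree
// split s, after restriction to the shared taxa `sh`; vanished or trivial
// restrictions can never be incompatible because one of the four
// intersections is empty
static inline bool incompat(M g, M s, M sh) {
  M g1 = m_and(g, sh), g2 = m_diff(sh, g);
  M s1 = m_and(s, sh), s2 = m_diff(sh, s);
  return !m_none(m_and(g1, s1)) && !m_none(m_and(g1, s2)) &&
         !m_none(m_and(g2, s1)) && !m_none(m_and(g2, s2));
}

// canonical restricted nontrivial split set of a tree on shared taxa
// (sorted and deduplicated); writes into a caller-owned buffer
static void restricted_splits(const std::vector<M>& sp, M sh,
                              std::vector<M>& out) {
  out.clear();
  int nsh = m_pc(sh);
  int low = m_lowest(sh);
  for (const M& s : sp) {
    M r = m_and(s, sh);
    int p = m_pc(r);
    if (p <= 1 || p >= nsh - 1) continue;
    if (!m_has(r, low)) r = m_diff(sh, r);
    out.push_back(r);
  }
  std::sort(out.begin(), out.end(), m_lt);
  out.erase(std::unique(out.begin(), out.end(), m_eq), out.end());
}

static int symdiff_sorted(const std::vector<M>& ra, const std::vector<M>& rb) {
  size_t i = 0, j = 0;
  int diff = 0;
  while (i < ra.size() && j < rb.size()) {
    if (m_eq(ra[i], rb[j])) { ++i; ++j; }
    else if (m_lt(ra[i], rb[j])) { ++diff; ++i; }
    else { ++diff; ++j; }
  }
  return diff + (int)(ra.size() - i) + (int)(rb.size() - j);
}

// RF distance between the two trees pruned to their shared taxa (= the
// MR(-) distance when S spans G)
static int d_minus_masks(const Tree& S, const Input& G) {
  M sh = m_and(S.tax, G.taxa);
  if (m_pc(sh) < 3) return 0;
  static thread_local std::vector<M> ra, rb;
  restricted_splits(S.sp, sh, ra);
  if (m_eq(sh, G.taxa)) return symdiff_sorted(ra, G.sorted);
  restricted_splits(G.splits, sh, rb);
  return symdiff_sorted(ra, rb);
}

// conflict counts: C = input splits incompatible with >= 1 supertree
// split, B = supertree splits incompatible with >= 1 input split
static void bc_counts(const Tree& S, const Input& G, int& B, int& C) {
  M sh = m_and(S.tax, G.taxa);
  B = 0; C = 0;
  if (m_pc(sh) < 3) return;
  std::vector<char> crow(G.splits.size(), 0);
  for (const M& s : S.sp) {
    bool bs = false;
    for (size_t i = 0; i < G.splits.size(); ++i) {
      if (incompat(G.splits[i], s, sh)) { bs = true; crow[i] = 1; }
    }
    if (bs) ++B;
  }
  for (char c : crow) C += c;
}

// ---------- incremental MR(-) scorer --------------------------------------
//
// For NNI evaluation the only change is one supertree split; the pruned-RF
// distance to each input then shifts by O(1) multiset updates.  Used for
// method MR(-) in sweeps and broadening; correctness is guarded by a full
// rescore of every returned tree.

struct MHash {
  size_t operator()(const M& x) const {
    uint64_t h = x.a * 0x9e3779b97f4a7c15ull ^ (x.b + 0x7f4a7c15u);
    h ^= h >> 33; h *= 0xff51afd7ed558ccdull; h ^= h >> 33;
    return (size_t)h;
  }
};
struct MEq {
  bool operator()(const M& x, const M& y) const { return m_eq(x, y); }
};

struct MinusState {
  struct PerInput {
    M sh;
    int nsh, low;
    std::unordered_set<M, MHash, MEq> gset;   // input's canonical splits
    std::unordered_map<M, int, MHash, MEq> cnt;  // restricted S splits
    int d;                                    // current symmetric difference
  };
  std::vector<PerInput> pi;
  int total;

  // canonical restriction of split side s for input i; returns false if
  // the restriction is trivial or vanishes
  bool canon(const PerInput& p, M s, M& out) const {
    M r = m_and(s, p.sh);
    int pc = m_pc(r);
    if (pc <= 1 || pc >= p.nsh - 1) return false;
    if (!m_has(r, p.low)) r = m_diff(p.sh, r);
    out = r;
    return true;
  }

  void init(const Tree& S, const std::vector<Input>& ins) {
    pi.clear();
    total = 0;
    for (const Input& G : ins) {
      PerInput p;
      p.sh = m_and(S.tax, G.taxa);
      p.nsh = m_pc(p.sh);
      p.low = p.nsh >= 1 ? m_lowest(p.sh) : 0;
      p.d = 0;
      if (p.nsh >= 3) {
        for (const M& g : G.sorted) p.gset.insert(g);
        for (const M& s : S.sp) {
          M r;
          if (canon(p, s, r)) p.cnt[r] += 1;
        }
        p.d = (int)p.gset.size();
        for (const auto& kv : p.cnt) {
          if (p.gset.count(kv.first)) p.d -= 1;  // matched
          else p.d += 1;                          // extra supertree split
        }
      }
      total += p.d;
      pi.push_back(std::move(p));
    }
  }

  // score change when replacing split side `from` with `to`
  int delta(M from, M to) const {
    int dd = 0;
    for (const PerInput& p : pi) {
      if (p.nsh < 3) continue;
      M rf, rt;
      bool hf = canon(p, from, rf), ht = canon(p, to, rt);
      if (hf && ht && m_eq(rf, rt)) continue;
      if (hf) {
        auto it = p.cnt.find(rf);
        if (it != p.cnt.end() && it->second == 1)
          dd += p.gset.count(rf) ? 1 : -1;       // last copy disappears
      }
      if (ht) {
        auto it = p.cnt.find(rt);
        if (it == p.cnt.end())
          dd += p.gset.count(rt) ? -1 : 1;       // new distinct split
      }
    }
    return dd;
  }

  void commit(M from, M to) {
    for (PerInput& p : pi) {
      if (p.nsh < 3) continue;
      M rf, rt;
      bool hf = canon(p, from, rf), ht = canon(p, to, rt);
      if (hf && ht && m_eq(rf, rt)) continue;
      if (hf) {
        auto it = p.cnt.find(rf);
        if (it != p.cnt.end()) {
          if (--(it->second) == 0) {
            p.cnt.erase(it);
            p.d += p.gset.count(rf) ? 1 : -1;
            total += p.gset.count(rf) ? 1 : -1;
          }
        }
      }
      if (ht) {
        auto it = p.cnt.find(rt);
        if (it == p.cnt.end()) {
          p.cnt[rt] = 1;
          p.d += p.gset.count(rt) ? -1 : 1;
          total += p.gset.count(rt) ? -1 : 1;
        } else {
          it->second += 1;
        }
      }
    }
  }
};

static int score_one(const Tree& S, const Input& G, int method) {
  if (method == 0) return d_minus_masks(S, G);
  int B, C;
  bc_counts(S, G, B, C);
  return method == 1 ? 2 * B : B + C;
}

static int score_total(const Tree& S, const std::vector<Input>& ins,
                       int method) {
  int tot = 0;
  for (const Input& G : ins) tot += score_one(S, G, method);
  return tot;
}

// ---------- tree surgery ---------------------------------------------------

// attach leaf x on the edge of `t` whose sides are A | (t.tax \ A)
static void attach_edge(Tree& t, int x, M A) {
  M B = m_diff(t.tax, A);
  M xb = m_bit(x);
  int foundA = -1, foundB = -1;
  for (size_t i = 0; i < t.sp.size(); ++i) {
    M& c = t.sp[i];
    if (m_eq(c, A)) { foundA = (int)i; continue; }
    if (m_eq(c, B)) { foundB = (int)i; continue; }
    if (!(m_subset(c, A) || m_subset(c, B))) c = m_or(c, xb);
  }
  t.tax = m_or(t.tax, xb);
  // the subdivided edge contributes the pair A|(B+x) and (A+x)|B
  if (foundA >= 0) t.sp.push_back(m_or(A, xb));
  else if (foundB >= 0) t.sp.push_back(A);
  else if (m_pc(A) == 1 && m_pc(B) >= 2) t.sp.push_back(m_or(A, xb));
  else if (m_pc(B) == 1 && m_pc(A) >= 2) t.sp.push_back(A);
  // (both sides singleton cannot happen for n >= 3)
}

// remove leaf x, suppressing the resulting degree-2 node
static void detach_leaf(Tree& t, int x) {
  M xb = m_bit(x);
  t.tax = m_diff(t.tax, xb);
  int n = m_pc(t.tax);
  int low = m_lowest(t.tax);
  std::vector<M> out;
  out.reserve(t.sp.size());
  for (M c : t.sp) {
    c = m_diff(c, xb);
    int p = m_pc(c);
    if (p <= 1 || p >= n - 1) continue;
    if (!m_has(c, low)) c = m_diff(t.tax, c);
    out.push_back(c);
  }
  std::sort(out.begin(), out.end(), m_lt);
  out.erase(std::unique(out.begin(), out.end(), m_eq), out.end());
  t.sp = out;
}

// the two NNI alternatives of split i in bifurcating tree t
static void nni_pair(const Tree& t, int i, M& v1, M& v2) {
  M A = t.sp[i], B = m_diff(t.tax, A);
  M A1 = m_zero(), B1 = m_zero();
  int bestA = 0, bestB = 0;
  for (size_t j = 0; j < t.sp.size(); ++j) {
    if ((int)j == i) continue;
    M c = t.sp[j];
    M cc = m_diff(t.tax, c);
    M d;
    if (m_subset(c, A)) d = c; else if (m_subset(cc, A)) d = cc; else d = m_zero();
    if (!m_none(d) && m_pc(d) < m_pc(A) && m_pc(d) > bestA) { bestA = m_pc(d); A1 = d; }
    if (m_subset(c, B)) d = c; else if (m_subset(cc, B)) d = cc; else d = m_zero();
    if (!m_none(d) && m_pc(d) < m_pc(B) && m_pc(d) > bestB) { bestB = m_pc(d); B1 = d; }
  }
  if (m_none(A1)) A1 = m_bit(m_lowest(A));
  if (m_none(B1)) B1 = m_bit(m_lowest(B));
  M A2 = m_diff(A, A1), B2 = m_diff(B, B1);
  v1 = m_or(A1, B1);
  v2 = m_or(A1, B2);
  (void)A2;
}

// canonical identity key of a tree (assumes a fixed taxon mask)
static std::string tree_canon_key(const Tree& t) {
  int low = m_lowest(t.tax);
  std::vector<M> cs;
  cs.reserve(t.sp.size());
  for (M c : t.sp) {
    if (!m_has(c, low)) c = m_diff(t.tax, c);
    cs.push_back(c);
  }
  std::sort(cs.begin(), cs.end(), m_lt);
  std::string key;
  key.reserve(cs.size() * 16);
  for (const M& c : cs) {
    key.append((const char*)&c.a, 8);
    key.append((const char*)&c.b, 8);
  }
  return key;
}

// ---------- step-wise addition --------------------------------------------

// candidate attachment edges of a partial tree: every inner split side
// plus every terminal edge
static void edge_sides(const Tree& t, std::vector<M>& out) {
  out.clear();
  out.reserve(t.sp.size() + m_pc(t.tax));
  for (const M& c : t.sp) out.push_back(c);
  for (int i = 0; i < 128; ++i)
    if (m_has(t.tax, i)) out.push_back(m_bit(i));
}

// insertion criterion for one candidate tree over the informative inputs:
// strategy 0 = summed pruned RF; strategy 1 = summed per-split
// contradiction count; accumulation aborts once `limit` is exceeded
static int insertion_cost(const Tree& cand, const std::vector<Input>& ins,
                          const std::vector<int>& informative, int strategy,
                          int limit) {
  int tot = 0;
  if (strategy == 0) {
    for (int gi : informative) {
      tot += d_minus_masks(cand, ins[gi]);
      if (tot > limit) return tot;
    }
  } else {
    for (const M& s : cand.sp) {
      for (int gi : informative) {
        const Input& G = ins[gi];
        M sh = m_and(cand.tax, G.taxa);
        if (m_pc(sh) < 3) continue;
        bool contra = false;
        for (const M& g : G.splits)
          if (incompat(g, s, sh)) { contra = true; break; }
        if (contra) ++tot;
      }
      if (tot > limit) return tot;
    }
  }
  return tot;
}

// insert taxon x into t at the best attachment point; `strategy` as above,
// ties resolved uniformly at random
static void stepwise_insert(Tree& t, int x, const std::vector<Input>& ins,
                            int strategy) {
  std::vector<int> informative;
  for (size_t gi = 0; gi < ins.size(); ++gi) {
    if (!m_has(ins[gi].taxa, x)) continue;
    if (m_pc(m_and(ins[gi].taxa, t.tax)) >= 3) informative.push_back((int)gi);
  }
  std::vector<M> edges;
  edge_sides(t, edges);
  int best = INT32_MAX, nbest = 0;
  M bestEdge = m_zero();
  Tree cand;
  for (const M& e : edges) {
    cand = t;
    attach_edge(cand, x, e);
    int c = informative.empty() ? 0 : insertion_cost(cand, ins, informative,
                                                     strategy, best);
    if (c < best) { best = c; nbest = 1; bestEdge = e; }
    else if (c == best) {
      ++nbest;
      if (rand_index(nbest) == 0) bestEdge = e;  // reservoir tie-break
    }
  }
  attach_edge(t, x, bestEdge);
}

// the quartet topology (as the side mask of the pair containing q[0]) most
// frequent among the inputs; returns false when no input resolves it
static bool quartet_vote(const std::vector<Input>& ins, const int q[4],
                         M& side) {
  M qm = m_or(m_or(m_bit(q[0]), m_bit(q[1])), m_or(m_bit(q[2]), m_bit(q[3])));
  int votes[3] = {0, 0, 0};
  M tops[3] = {m_or(m_bit(q[0]), m_bit(q[1])),
               m_or(m_bit(q[0]), m_bit(q[2])),
               m_or(m_bit(q[0]), m_bit(q[3]))};
  for (const Input& G : ins) {
    if (!m_subset(qm, G.taxa)) continue;
    for (const M& s : G.splits) {
      M r = m_and(s, qm);
      int p = m_pc(r);
      if (p != 2) continue;
      if (!m_has(r, q[0])) r = m_diff(qm, r);
      for (int k = 0; k < 3; ++k)
        if (m_eq(r, tops[k])) { ++votes[k]; break; }
      break;  // a tree resolves a quartet at most one way
    }
  }
  int mx = std::max(votes[0], std::max(votes[1], votes[2]));
  if (mx == 0) return false;
  int nb = 0;
  for (int k = 0; k < 3; ++k) {
    if (votes[k] == mx) {
      ++nb;
      if (rand_index(nb) == 0) side = tops[k];
    }
  }
  return true;
}

// build a step-wise addition tree for the given taxa (subset of the
// universe); processes a random taxon order
static Tree stepwise_tree(const std::vector<Input>& ins, M want, int method) {
  std::vector<int> order;
  for (int i = 0; i < 128; ++i) if (m_has(want, i)) order.push_back(i);
  shuffle_vec(order);
  int n = (int)order.size();
  if (n < 4) stop("need at least 4 taxa");
  // seed quartet: first four of the order if any input resolves them;
  // otherwise the four earliest-in-order taxa contained in one input
  int q[4] = {order[0], order[1], order[2], order[3]};
  M side;
  bool ok = quartet_vote(ins, q, side);
  if (!ok) {
    int bestpos = INT32_MAX;
    int cand[4];
    for (const Input& G : ins) {
      if (G.ntax < 4) continue;
      int got = 0, pos = -1, c[4];
      for (int idx = 0; idx < n && got < 4; ++idx) {
        if (m_has(G.taxa, order[idx])) { c[got++] = order[idx]; pos = idx; }
      }
      if (got == 4 && pos < bestpos) {
        bestpos = pos;
        for (int k = 0; k < 4; ++k) cand[k] = c[k];
      }
    }
    if (bestpos < INT32_MAX) {
      for (int k = 0; k < 4; ++k) q[k] = cand[k];
      ok = quartet_vote(ins, q, side);
      // move the quartet to the front of the order, keeping relative order
      std::vector<int> rest;
      for (int idx = 0; idx < n; ++idx) {
        int t = order[idx];
        if (t != q[0] && t != q[1] && t != q[2] && t != q[3])
          rest.push_back(t);
      }
      for (int k = 0; k < 4; ++k) order[k] = q[k];
      for (int k = 0; k < (int)rest.size(); ++k) order[k + 4] = rest[k];
    }
  }
  if (!ok) {
    // no input resolves any quartet: start from a random topology
    int pick = rand_index(3);
    side = m_or(m_bit(q[0]), m_bit(q[pick + 1]));
  }
  Tree t;
  t.tax = m_or(m_or(m_bit(q[0]), m_bit(q[1])), m_or(m_bit(q[2]), m_bit(q[3])));
  t.sp.push_back(side);
  int parity = 0;
  for (int idx = 4; idx < n; ++idx) {
    int strategy = method == 0 ? 0 : (method == 1 ? 1 : (parity++ % 2));
    stepwise_insert(t, order[idx], ins, strategy);
  }
  return t;
}

// reinsert the given taxa (random order) into t by step-wise addition
static void reinsert_taxa(Tree& t, std::vector<int> taxa,
                          const std::vector<Input>& ins, int method) {
  shuffle_vec(taxa);
  int parity = 0;
  for (int x : taxa) {
    int strategy = method == 0 ? 0 : (method == 1 ? 1 : (parity++ % 2));
    stepwise_insert(t, x, ins, strategy);
  }
}

// one taxa-deletion-reinsertion move
static Tree tdr_move(const Tree& t, const std::vector<Input>& ins,
                     int method, double fraction) {
  int n = m_pc(t.tax);
  int k = (int)std::ceil(fraction * n);
  if (n - k < 4) k = n - 4;
  if (k <= 0) return t;
  std::vector<int> taxa;
  for (int i = 0; i < 128; ++i) if (m_has(t.tax, i)) taxa.push_back(i);
  shuffle_vec(taxa);
  taxa.resize(k);
  Tree out = t;
  for (int x : taxa) detach_leaf(out, x);
  reinsert_taxa(out, taxa, ins, method);
  return out;
}

// ---------- NNI sweep ------------------------------------------------------

// hill-climb by NNI until locally optimal; returns the number of
// replacements performed and fills `alts` with distinct equal-scoring
// neighbours of the final tree
static int nni_sweep_core(Tree& t, const std::vector<Input>& ins, int method,
                          int& score, std::vector<Tree>& alts) {
  int l = (int)t.sp.size();
  bool fast = (method == 0);
  MinusState st;
  if (fast) { st.init(t, ins); score = st.total; }
  else score = score_total(t, ins, method);
  int repl = 0;
  bool improved = true;
  std::vector<int> perm(l);
  for (int i = 0; i < l; ++i) perm[i] = i;
  while (improved) {
    improved = false;
    shuffle_vec(perm);
    for (int pi = 0; pi < l; ++pi) {
      int i = perm[pi];
      M v1, v2;
      nni_pair(t, i, v1, v2);
      M keep = t.sp[i];
      for (M v : {v1, v2}) {
        int sc;
        if (fast) sc = score + st.delta(keep, v);
        else { t.sp[i] = v; sc = score_total(t, ins, method); t.sp[i] = keep; }
        if (sc < score) {
          if (fast) st.commit(keep, v);
          t.sp[i] = v;
          keep = v;
          score = sc;
          ++repl;
          improved = true;
        }
      }
    }
  }
  // collect equal-scoring neighbours of the local optimum
  alts.clear();
  std::unordered_set<std::string> seen;
  seen.insert(tree_canon_key(t));
  for (int i = 0; i < l; ++i) {
    M v1, v2;
    nni_pair(t, i, v1, v2);
    M keep = t.sp[i];
    for (M v : {v1, v2}) {
      int sc;
      if (fast) sc = score + st.delta(keep, v);
      else { t.sp[i] = v; sc = score_total(t, ins, method); t.sp[i] = keep; }
      if (sc == score) {
        t.sp[i] = v;
        std::string k = tree_canon_key(t);
        if (seen.insert(k).second) alts.push_back(t);
        t.sp[i] = keep;
      }
    }
  }
  return repl;
}

// ---------- conversions ----------------------------------------------------

static std::vector<Input> make_inputs_cpp(List inputs) {
  std::vector<Input> out;
  for (R_xlen_t i = 0; i < inputs.size(); ++i) {
    List g = inputs[i];
    IntegerVector tx = g["taxa"];
    List sp = g["splits"];
    Input G;
    G.taxa = m_zero();
    for (int t : tx) G.taxa = m_or(G.taxa, m_bit(t));
    G.ntax = (int)tx.size();
    for (R_xlen_t j = 0; j < sp.size(); ++j) {
      IntegerVector side = sp[j];
      M s = m_zero();
      for (int t : side) s = m_or(s, m_bit(t));
      G.splits.push_back(s);
    }
    restricted_splits(G.splits, G.taxa, G.sorted);
    out.push_back(G);
  }
  return out;
}

static Tree make_tree_cpp(List tr) {
  IntegerVector tx = tr["taxa"];
  List sp = tr["splits"];
  Tree t;
  t.tax = m_zero();
  for (int i : tx) t.tax = m_or(t.tax, m_bit(i));
  for (R_xlen_t j = 0; j < sp.size(); ++j) {
    IntegerVector side = sp[j];
    M s = m_zero();
    for (int i : side) s = m_or(s, m_bit(i));
    t.sp.push_back(s);
  }
  return t;
}

static List tree_to_r(const Tree& t) {
  IntegerVector tx;
  for (int i = 0; i < 128; ++i) if (m_has(t.tax, i)) tx.push_back(i);
  List sp(t.sp.size());
  for (size_t j = 0; j < t.sp.size(); ++j) {
    IntegerVector side;
    for (int i = 0; i < 128; ++i) if (m_has(t.sp[j], i)) side.push_back(i);
    sp[j] = side;
  }
  return List::create(_["taxa"] = tx, _["splits"] = sp);
}

// ---------- exported entry points -----------------------------------------

// [[Rcpp::export]]
int cpp_score(List tree, List inputs, int method) {
  Tree t = make_tree_cpp(tree);
  std::vector<Input> ins = make_inputs_cpp(inputs);
  return score_total(t, ins, method);
}

// [[Rcpp::export]]
List cpp_stepwise(List inputs, IntegerVector taxa, int method) {
  std::vector<Input> ins = make_inputs_cpp(inputs);
  M want = m_zero();
  for (int t : taxa) want = m_or(want, m_bit(t));
  Tree t = stepwise_tree(ins, want, method);
  return tree_to_r(t);
}

// [[Rcpp::export]]
List cpp_tdr(List tree, List inputs, int method, double fraction) {
  Tree t = make_tree_cpp(tree);
  std::vector<Input> ins = make_inputs_cpp(inputs);
  Tree out = tdr_move(t, ins, method, fraction);
  return tree_to_r(out);
}

// [[Rcpp::export]]
List cpp_nni_sweep(List tree, List inputs, int method) {
  Tree t = make_tree_cpp(tree);
  std::vector<Input> ins = make_inputs_cpp(inputs);
  int score = 0;
  std::vector<Tree> alts;
  int repl = nni_sweep_core(t, ins, method, score, alts);
  List out(alts.size() + 1);
  out[0] = tree_to_r(t);
  for (size_t i = 0; i < alts.size(); ++i) out[i + 1] = tree_to_r(alts[i]);
  return List::create(_["trees"] = out, _["score"] = score,
                      _["replacements"] = repl);
}

// pool of best-scoring trees with canonical-key deduplication
struct Pool {
  std::vector<Tree> trees;
  std::unordered_set<std::string> keys;
  bool add(const Tree& t) {
    std::string k = tree_canon_key(t);
    if (!keys.insert(k).second) return false;
    trees.push_back(t);
    return true;
  }
  void clear() { trees.clear(); keys.clear(); }
};

// strict consensus (canonical split intersection) over a set of trees
static std::vector<M> pool_consensus(const std::vector<Tree>& trees) {
  std::vector<M> cons;
  if (trees.empty()) return cons;
  int low = m_lowest(trees[0].tax);
  for (M c : trees[0].sp) {
    if (!m_has(c, low)) c = m_diff(trees[0].tax, c);
    cons.push_back(c);
  }
  std::sort(cons.begin(), cons.end(), m_lt);
  for (size_t t = 1; t < trees.size() && !cons.empty(); ++t) {
    std::vector<M> cur;
    for (M c : trees[t].sp) {
      if (!m_has(c, low)) c = m_diff(trees[t].tax, c);
      cur.push_back(c);
    }
    std::sort(cur.begin(), cur.end(), m_lt);
    std::vector<M> keep;
    std::set_intersection(cons.begin(), cons.end(), cur.begin(), cur.end(),
                          std::back_inserter(keep), m_lt);
    cons = keep;
  }
  return cons;
}

// [[Rcpp::export]]
List cpp_run_search(List inputs, IntegerVector taxa, int method,
                    double tdr_fraction, int max_iter, int discard_limit,
                    int max_trees, int max_return, Nullable<List> start) {
  std::vector<Input> ins = make_inputs_cpp(inputs);
  M want = m_zero();
  for (int t : taxa) want = m_or(want, m_bit(t));
  int n = m_pc(want);
  int l = n - 3;
  if (max_iter <= 0) max_iter = l * l;
  if (discard_limit <= 0) discard_limit = l;

  Tree t;
  if (start.isNotNull()) t = make_tree_cpp(List(start.get()));
  else t = stepwise_tree(ins, want, method);

  int iter = 0, best = 0;
  std::vector<Tree> alts;
  iter += nni_sweep_core(t, ins, method, best, alts);

  Pool pool;
  pool.add(t);
  for (const Tree& a : alts) pool.add(a);
  std::unordered_set<std::string> seen;       // all trees visited
  seen.insert(tree_canon_key(t));
  std::unordered_set<std::string> analyzed;   // trees already swept from
  analyzed.insert(tree_canon_key(t));
  bool truncated = false;

  // exploration stage: TDR restarts, each followed by an NNI hill-climb
  Tree incumbent = t;
  int discards = 0, n_tdr = 0;
  while (iter < max_iter && discards < discard_limit) {
    Tree t2 = tdr_move(incumbent, ins, method, tdr_fraction);
    ++iter; ++n_tdr;
    if (!seen.insert(tree_canon_key(t2)).second) { ++discards; continue; }
    int sc = 0;
    int repl = nni_sweep_core(t2, ins, method, sc, alts);
    iter += repl;
    seen.insert(tree_canon_key(t2));
    bool newfound = false;
    if (sc < best) {
      best = sc;
      pool.clear();
      analyzed.clear();
      pool.add(t2);
      for (const Tree& a : alts) pool.add(a);
      analyzed.insert(tree_canon_key(t2));
      newfound = true;
    } else if (sc == best) {
      if (pool.add(t2)) newfound = true;
      analyzed.insert(tree_canon_key(t2));
      for (const Tree& a : alts)
        if ((int)pool.trees.size() < max_trees && pool.add(a)) newfound = true;
    }
    if (repl == 0 && !newfound) ++discards; else discards = 0;
    incumbent = t2;
    if ((int)pool.trees.size() >= max_trees) { truncated = true; break; }
  }

  // broadening stage: NNI-explore every best tree not yet analyzed so the
  // whole optimal neighbourhood is visited
  size_t qpos = 0;
  bool fast = (method == 0);
  MinusState st;
  while (qpos < pool.trees.size()) {
    if ((int)pool.trees.size() > max_trees) { truncated = true; break; }
    Tree cur = pool.trees[qpos++];
    std::string ck = tree_canon_key(cur);
    if (!analyzed.insert(ck).second) continue;
    if (fast) st.init(cur, ins);
    int l2 = (int)cur.sp.size();
    for (int i = 0; i < l2; ++i) {
      M v1, v2;
      nni_pair(cur, i, v1, v2);
      M keep = cur.sp[i];
      for (M v : {v1, v2}) {
        cur.sp[i] = v;
        int sc = fast ? best + st.delta(keep, v)
                      : score_total(cur, ins, method);
        if (sc < best) {
          // a strictly better tree reachable from the pool: restart
          best = sc;
          Tree t3 = cur;
          int repl = nni_sweep_core(t3, ins, method, sc, alts);
          (void)repl;
          best = sc;
          pool.clear();
          analyzed.clear();
          pool.add(t3);
          for (const Tree& a : alts) pool.add(a);
          analyzed.insert(tree_canon_key(t3));
          qpos = 0;
          i = l2; break;
        } else if (sc == best) {
          pool.add(cur);
        }
        cur.sp[i] = keep;
      }
    }
  }

  // strict consensus over the complete pool; only up to `max_return`
  // trees are materialized as R objects (large optimal sets would
  // otherwise exhaust memory)
  std::vector<M> cons = pool_consensus(pool.trees);
  List consensus((int)cons.size());
  for (size_t j = 0; j < cons.size(); ++j) {
    IntegerVector side;
    for (int i = 0; i < 128; ++i) if (m_has(cons[j], i)) side.push_back(i);
    consensus[j] = side;
  }
  int nret = std::min((int)pool.trees.size(), max_return);
  List trees(nret);
  for (int i = 0; i < nret; ++i) trees[i] = tree_to_r(pool.trees[i]);
  return List::create(_["best_score"] = best, _["trees"] = trees,
                      _["n_optimal"] = (int)pool.trees.size(),
                      _["consensus"] = consensus,
                      _["iterations"] = iter, _["n_tdr"] = n_tdr,
                      _["discards"] = discards,
                      _["truncated"] = truncated);
}
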