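// Brute-force distance oracle: breadth-first search over genome states
// under DCJ operations and (optionally) substitutions of unique-marker
// blocks.  Completely independent of the closed-form distance: genomes are
// plain signed-integer sequences, moves are generated from first
// principles, and the target is recognised by canonical-form equality.
//
// Move set for substitutions (a pragmatic restriction that always yields a
// valid sorting scenario, hence an upper bound): removed blocks are
// (maximal) contiguous blocks of markers absent from the target genome;
// inserted blocks appear contiguously, with orientation, in the target and
// contain no marker already present.  `widen` additionally allows
// non-maximal removed blocks.

#include <Rcpp.h>
#include <algorithm>
#include <set>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

struct Genome {
  std::vector<std::vector<int>> chr;  // signed marker ids, 1-based
  std::vector<uint8_t> circ;
};

static std::vector<int> revneg(const std::vector<int>& v) {
  std::vector<int> r(v.rbegin(), v.rend());
  for (auto& x : r) x = -x;
  return r;
}

static std::vector<int> canon_chrom(const std::vector<int>& v, bool circ) {
  if (!circ) return std::min(v, revneg(v));
  std::vector<int> best;
  for (int dir = 0; dir < 2; ++dir) {
    std::vector<int> w = dir ? revneg(v) : v;
    const size_t n = w.size();
    for (size_t r = 0; r < n; ++r) {
      std::vector<int> rot(n);
      for (size_t i = 0; i < n; ++i) rot[i] = w[(r + i) % n];
      if (best.empty() || rot < best) best = rot;
    }
  }
  return best;
}

static std::string genome_key(const Genome& g) {
  std::vector<std::string> parts;
  for (size_t i = 0; i < g.chr.size(); ++i) {
    std::vector<int> c = canon_chrom(g.chr[i], g.circ[i]);
    std::string s(g.circ[i] ? "C" : "L");
    for (int x : c) { s += ','; s += std::to_string(x); }
    parts.push_back(s);
  }
  std::sort(parts.begin(), parts.end());
  std::string key;
  for (auto& p : parts) { key += p; key += ';'; }
  return key;
}

// extremities: marker m -> tail 2m, head 2m+1
static inline int etail(int m) { return 2 * m; }
static inline int ehead(int m) { return 2 * m + 1; }
static inline int esib(int e) { return e ^ 1; }
static inline int emark(int e) { return e >> 1; }
static inline int left_ext(int v)  { return v > 0 ? etail(v) : ehead(-v); }
static inline int right_ext(int v) { return v > 0 ? ehead(v) : etail(-v); }

struct Matching {
  std::vector<std::pair<int, int>> adj;
  std::vector<int> tel;
  std::vector<int> markers;  // present marker ids
};

static Matching to_matching(const Genome& g) {
  Matching m;
  std::unordered_set<int> mk;
  for (size_t ci = 0; ci < g.chr.size(); ++ci) {
    const auto& c = g.chr[ci];
    for (int v : c) mk.insert(std::abs(v));
    for (size_t i = 0; i + 1 < c.size(); ++i)
      m.adj.push_back({right_ext(c[i]), left_ext(c[i + 1])});
    if (g.circ[ci]) m.adj.push_back({right_ext(c.back()), left_ext(c.front())});
    else { m.tel.push_back(left_ext(c.front())); m.tel.push_back(right_ext(c.back())); }
  }
  m.markers.assign(mk.begin(), mk.end());
  std::sort(m.markers.begin(), m.markers.end());
  return m;
}

static Genome from_matching(const Matching& m) {
  std::unordered_map<int, int> partner;
  for (auto& a : m.adj) { partner[a.first] = a.second; partner[a.second] = a.first; }
  std::unordered_set<int> seen;
  Genome g;
  std::vector<int> tel = m.tel;
  std::sort(tel.begin(), tel.end());
  for (int t : tel) {
    if (seen.count(emark(t))) continue;
    std::vector<int> c;
    int e = t;
    while (true) {
      c.push_back(e % 2 == 0 ? emark(e) : -emark(e));  // tail entry = forward
      seen.insert(emark(e));
      auto it = partner.find(esib(e));
      if (it == partner.end()) break;
      e = it->second;
    }
    g.chr.push_back(c);
    g.circ.push_back(0);
  }
  for (int mk : m.markers) {
    if (seen.count(mk)) continue;
    std::vector<int> c;
    int e = etail(mk);
    while (true) {
      c.push_back(e % 2 == 0 ? emark(e) : -emark(e));
      seen.insert(emark(e));
      auto it = partner.find(esib(e));
      int nxt = it->second;  // circular: always matched
      if (nxt == etail(mk)) break;
      e = nxt;
    }
    g.chr.push_back(c);
    g.circ.push_back(1);
  }
  return g;
}

static void push_state(std::vector<Genome>& out, Genome&& g) { out.push_back(std::move(g)); }

static void dcj_neighbors(const Genome& g, std::vector<Genome>& out) {
  Matching m = to_matching(g);
  const size_t na = m.adj.size(), nt = m.tel.size();
  for (size_t i = 0; i < na; ++i)
    for (size_t j = i + 1; j < na; ++j)
      for (int mode = 0; mode < 2; ++mode) {
        Matching m2 = m;
        auto a = m.adj[i], b = m.adj[j];
        m2.adj.erase(m2.adj.begin() + j);
        m2.adj.erase(m2.adj.begin() + i);
        if (mode == 0) { m2.adj.push_back({a.first, b.first});  m2.adj.push_back({a.second, b.second}); }
        else           { m2.adj.push_back({a.first, b.second}); m2.adj.push_back({a.second, b.first}); }
        push_state(out, from_matching(m2));
      }
  for (size_t i = 0; i < na; ++i)
    for (size_t t = 0; t < nt; ++t)
      for (int mode = 0; mode < 2; ++mode) {
        Matching m2 = m;
        auto a = m.adj[i];
        int te = m.tel[t];
        m2.adj.erase(m2.adj.begin() + i);
        m2.tel.erase(m2.tel.begin() + t);
        if (mode == 0) { m2.adj.push_back({a.first, te}); m2.tel.push_back(a.second); }
        else           { m2.adj.push_back({a.second, te}); m2.tel.push_back(a.first); }
        push_state(out, from_matching(m2));
      }
  for (size_t t1 = 0; t1 < nt; ++t1)
    for (size_t t2 = t1 + 1; t2 < nt; ++t2) {
      Matching m2 = m;
      int a = m.tel[t1], b = m.tel[t2];
      m2.tel.erase(m2.tel.begin() + t2);
      m2.tel.erase(m2.tel.begin() + t1);
      m2.adj.push_back({a, b});
      push_state(out, from_matching(m2));
    }
  for (size_t i = 0; i < na; ++i) {
    Matching m2 = m;
    auto a = m.adj[i];
    m2.adj.erase(m2.adj.begin() + i);
    m2.tel.push_back(a.first);
    m2.tel.push_back(a.second);
    push_state(out, from_matching(m2));
  }
}

// insertable content: every signed arrangement of every non-empty subset
// of the target-unique markers (an optimal scenario may insert markers in
// an order that only later DCJs turn into the target order, so insertions
// cannot be restricted to blocks that are contiguous in the target)
struct SubCtx {
  std::unordered_set<int> target_markers;                 // ids present in B
  std::vector<int> pool;                                  // target-unique ids
  std::vector<std::vector<int>> blocks;                   // insertable blocks
};

static SubCtx make_ctx(const Genome& a, const Genome& b) {
  SubCtx ctx;
  std::unordered_set<int> amk;
  for (size_t ci = 0; ci < a.chr.size(); ++ci)
    for (int v : a.chr[ci]) amk.insert(std::abs(v));
  for (size_t ci = 0; ci < b.chr.size(); ++ci)
    for (int v : b.chr[ci]) ctx.target_markers.insert(std::abs(v));
  std::set<int> pool_set;
  for (size_t ci = 0; ci < b.chr.size(); ++ci)
    for (int v : b.chr[ci])
      if (!amk.count(std::abs(v))) pool_set.insert(std::abs(v));
  ctx.pool.assign(pool_set.begin(), pool_set.end());
  const size_t n = ctx.pool.size();
  if (n > 6) Rcpp::stop("oracle: too many target-unique markers");
  std::set<std::vector<int>> seen;
  // enumerate subsets, permutations and sign patterns; canonical up to
  // reversal-with-negation (insertion tries one orientation per block)
  for (unsigned mask = 1; mask < (1u << n); ++mask) {
    std::vector<int> sub;
    for (size_t i = 0; i < n; ++i)
      if (mask & (1u << i)) sub.push_back(ctx.pool[i]);
    std::sort(sub.begin(), sub.end());
    do {
      const size_t k = sub.size();
      for (unsigned smask = 0; smask < (1u << k); ++smask) {
        std::vector<int> blk(k);
        for (size_t i = 0; i < k; ++i)
          blk[i] = (smask & (1u << i)) ? -sub[i] : sub[i];
        std::vector<int> canon = std::min(blk, revneg(blk));
        if (seen.insert(canon).second) ctx.blocks.push_back(canon);
      }
    } while (std::next_permutation(sub.begin(), sub.end()));
  }
  return ctx;
}

static bool block_absent(const std::vector<int>& blk, const std::unordered_set<int>& present) {
  for (int v : blk)
    if (present.count(std::abs(v))) return false;
  return true;
}

static void splice_sub(const Genome& g, size_t ci, const std::vector<size_t>& drop,
                       size_t insert_at, const std::vector<int>& ins,
                       std::vector<Genome>& out) {
  // replace positions `drop` (contiguous, possibly wrapping) of chromosome
  // ci by `ins` (both orientations), at the gap where the block sat
  const auto& c = g.chr[ci];
  std::vector<uint8_t> del(c.size(), 0);
  for (size_t p : drop) del[p] = 1;
  std::vector<int> kept;
  // rebuild starting just after the dropped block so the gap is at `kept`
  // position `insert_at` == gap index in the rebuilt order
  for (size_t off = 0; off < c.size(); ++off) {
    size_t p = (insert_at + off) % c.size();
    if (!del[p]) kept.push_back(c[p]);
  }
  for (int dir = 0; dir < (ins.empty() ? 1 : 2); ++dir) {
    std::vector<int> blk = dir ? revneg(ins) : ins;
    Genome g2 = g;
    std::vector<int> nc;
    if (g.circ[ci]) {
      nc = blk;  // gap is at the start of `kept` rotation
      nc.insert(nc.end(), kept.begin(), kept.end());
    } else {
      // linear: kept order must stay the original order; insert_at is the
      // original index of the first dropped position
      nc.clear();
      for (size_t p = 0; p < c.size(); ++p) {
        if (p == insert_at) nc.insert(nc.end(), blk.begin(), blk.end());
        if (!del[p]) nc.push_back(c[p]);
      }
      if (insert_at == c.size()) nc.insert(nc.end(), blk.begin(), blk.end());
    }
    if (nc.empty()) { g2.chr.erase(g2.chr.begin() + ci); g2.circ.erase(g2.circ.begin() + ci); }
    else g2.chr[ci] = nc;
    push_state(out, std::move(g2));
  }
}

static void sub_neighbors(const Genome& g, const SubCtx& ctx, bool widen,
                          std::vector<Genome>& out) {
  std::unordered_set<int> present;
  for (size_t ci = 0; ci < g.chr.size(); ++ci)
    for (int v : g.chr[ci]) present.insert(std::abs(v));
  // candidate insert blocks available now
  std::vector<size_t> avail;
  for (size_t bi = 0; bi < ctx.blocks.size(); ++bi)
    if (block_absent(ctx.blocks[bi], present)) avail.push_back(bi);

  // --- removal sites: maximal contiguous runs of target-absent markers
  for (size_t ci = 0; ci < g.chr.size(); ++ci) {
    const auto& c = g.chr[ci];
    const size_t L = c.size();
    std::vector<uint8_t> rm(L);
    bool all_rm = true;
    for (size_t i = 0; i < L; ++i) {
      rm[i] = !ctx.target_markers.count(std::abs(c[i]));
      all_rm = all_rm && rm[i];
    }
    std::vector<std::pair<size_t, size_t>> segs;
    if (all_rm) {
      if (L) segs.push_back({0, L});
    } else if (!g.circ[ci]) {
      size_t i = 0;
      while (i < L) {
        if (!rm[i]) { ++i; continue; }
        size_t j = i;
        while (j < L && rm[j]) ++j;
        segs.push_back({i, j - i});
        i = j;
      }
    } else {
      for (size_t i = 0; i < L; ++i) {
        if (!rm[i] || rm[(i + L - 1) % L]) continue;
        size_t len = 0;
        while (rm[(i + len) % L]) ++len;
        segs.push_back({i, len});
      }
    }
    for (auto& sg : segs) {
      std::vector<std::pair<size_t, size_t>> windows;  // (start, len)
      if (widen) {
        for (size_t off = 0; off < sg.second; ++off)
          for (size_t len = 1; off + len <= sg.second; ++len)
            windows.push_back({(sg.first + off) % L, len});
      } else {
        windows.push_back(sg);
      }
      for (auto& w : windows) {
        std::vector<size_t> drop(w.second);
        for (size_t i = 0; i < w.second; ++i) drop[i] = (w.first + i) % L;
        bool whole = (w.second == L);
        // pure deletion
        if (whole) {
          Genome g2 = g;
          g2.chr.erase(g2.chr.begin() + ci);
          g2.circ.erase(g2.circ.begin() + ci);
          push_state(out, std::move(g2));
        } else {
          splice_sub(g, ci, drop, (w.first + w.second) % std::max<size_t>(L, 1),
                     std::vector<int>(), out);
        }
        // substitution by each available block
        for (size_t bi : avail) {
          const auto& blk = ctx.blocks[bi];
          if (whole) {
            // whole-chromosome substitution keeps the topology
            for (int dir = 0; dir < 2; ++dir) {
              Genome g2 = g;
              g2.chr[ci] = dir ? revneg(blk) : blk;
              push_state(out, std::move(g2));
            }
          } else {
            size_t gap = g.circ[ci] ? (w.first + w.second) % L : w.first;
            splice_sub(g, ci, drop, gap, blk, out);
          }
        }
      }
    }
  }
  // --- pure insertions
  for (size_t bi : avail) {
    const auto& blk = ctx.blocks[bi];
    for (size_t ci = 0; ci < g.chr.size(); ++ci) {
      const auto& c = g.chr[ci];
      size_t npos = g.circ[ci] ? c.size() : c.size() + 1;
      for (size_t pos = 0; pos < npos; ++pos)
        for (int dir = 0; dir < 2; ++dir) {
          std::vector<int> b2 = dir ? revneg(blk) : blk;
          Genome g2 = g;
          std::vector<int> nc;
          if (g.circ[ci]) {
            for (size_t i = 0; i <= pos; ++i) nc.push_back(c[i]);
            nc.insert(nc.end(), b2.begin(), b2.end());
            for (size_t i = pos + 1; i < c.size(); ++i) nc.push_back(c[i]);
          } else {
            for (size_t i = 0; i < pos; ++i) nc.push_back(c[i]);
            nc.insert(nc.end(), b2.begin(), b2.end());
            for (size_t i = pos; i < c.size(); ++i) nc.push_back(c[i]);
          }
          g2.chr[ci] = nc;
          push_state(out, std::move(g2));
        }
    }
    // as a new chromosome
    Genome gl = g;
    gl.chr.push_back(blk); gl.circ.push_back(0);
    push_state(out, std::move(gl));
    Genome gc = g;
    gc.chr.push_back(blk); gc.circ.push_back(1);
    push_state(out, std::move(gc));
  }
}


// admissible pruning bound: project a genome onto the common markers
// (adjacencies between consecutive common extremities, plus their
// chromosome-end telomeres).  A substitution never changes the
// projection; a DCJ changes at most two projected elements, so
// ceil(missing/2) never overestimates the remaining DCJ work, and the
// content indicator never overestimates the remaining substitutions.
static std::vector<long long> projected_features(const Genome& g,
                                                 const std::unordered_set<int>& common) {
  std::vector<long long> feats;
  auto enc = [](int e1, int e2) {
    if (e1 > e2) std::swap(e1, e2);
    return (long long)e1 * 1000000LL + e2;  // 0 encodes a telomere
  };
  for (size_t ci = 0; ci < g.chr.size(); ++ci) {
    const auto& c = g.chr[ci];
    std::vector<int> pos;
    for (size_t i = 0; i < c.size(); ++i)
      if (common.count(std::abs(c[i]))) pos.push_back((int)i);
    if (pos.empty()) continue;
    for (size_t k = 0; k + 1 < pos.size(); ++k)
      feats.push_back(enc(right_ext(c[pos[k]]), left_ext(c[pos[k + 1]])));
    if (g.circ[ci]) {
      feats.push_back(enc(right_ext(c[pos.back()]), left_ext(c[pos.front()])));
    } else {
      feats.push_back(enc(0, left_ext(c[pos.front()])));
      feats.push_back(enc(0, right_ext(c[pos.back()])));
    }
  }
  std::sort(feats.begin(), feats.end());
  return feats;
}

static int missing_features(const std::vector<long long>& state_f,
                            const std::vector<long long>& target_f) {
  size_t i = 0, j = 0; int missing = 0;
  while (j < target_f.size()) {
    if (i >= state_f.size() || state_f[i] > target_f[j]) { ++missing; ++j; }
    else if (state_f[i] < target_f[j]) ++i;
    else { ++i; ++j; }
  }
  return missing;
}

static Genome list_to_genome(List chrs, LogicalVector circ) {
  Genome g;
  for (int i = 0; i < chrs.size(); ++i) {
    IntegerVector v = chrs[i];
    g.chr.push_back(std::vector<int>(v.begin(), v.end()));
    g.circ.push_back(circ[i] ? 1 : 0);
  }
  return g;
}

// [[Rcpp::export]]
int oracle_search_cpp(List chrA, LogicalVector circA, List chrB, LogicalVector circB,
                      int max_depth, bool dcj_only, bool widen, double node_cap) {
  Genome a = list_to_genome(chrA, circA);
  Genome b = list_to_genome(chrB, circB);
  SubCtx ctx;
  if (!dcj_only) ctx = make_ctx(a, b);
  std::unordered_set<int> amk, common;
  for (auto& c : a.chr) for (int v : c) amk.insert(std::abs(v));
  for (auto& c : b.chr) for (int v : c)
    if (amk.count(std::abs(v))) common.insert(std::abs(v));
  std::vector<long long> target_f = projected_features(b, common);
  std::string goal = genome_key(b);
  if (genome_key(a) == goal) return 0;
  std::unordered_set<std::string> visited;
  std::vector<Genome> frontier{a};
  visited.insert(genome_key(a));
  for (int depth = 1; depth <= max_depth; ++depth) {
    std::vector<Genome> next;
    for (const Genome& st : frontier) {
      std::vector<Genome> nb;
      dcj_neighbors(st, nb);
      if (!dcj_only) sub_neighbors(st, ctx, widen, nb);
      for (Genome& g2 : nb) {
        std::string k = genome_key(g2);
        if (k == goal) return depth;
        if (visited.count(k)) continue;
        // DCJs fix at most two projected adjacencies and never change
        // content; substitutions fix content and never the projection,
        // so the two lower-bound terms add
        int miss = missing_features(projected_features(g2, common), target_f);
        int content = 0;
        if (!dcj_only) {
          std::unordered_set<int> present;
          for (auto& c : g2.chr) for (int v : c) present.insert(std::abs(v));
          bool wrong = false;
          for (int m : ctx.pool) if (!present.count(m)) { wrong = true; break; }
          if (!wrong) for (int m : present) if (!ctx.target_markers.count(m)) { wrong = true; break; }
          content = wrong ? 1 : 0;
        }
        if (depth + (miss + 1) / 2 + content > max_depth) continue;
        visited.insert(k);
        next.push_back(std::move(g2));
        if ((double)visited.size() > node_cap) return -3;
      }
    }
    if (next.empty()) return -1;
    frontier = std::move(next);
  }
  return -1;
}
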