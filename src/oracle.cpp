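// Brute-force reference search for the restricted DCJ-indel halving
// distance.  Breadth-first search over genome states reachable by DCJ
// operations, deletions of contiguous singular segments, and insertions of
// the single missing homolog of a singular marker.  States are deduplicated
// by a canonical form invariant under chromosome order, rotation of
// circular chromosomes and reflection.
//
// Marker instances are integers 1..N0; the inserted homolog of a singular
// marker m is assigned the id m + N0, so the partner relation is a function
// of the id alone and states are fully described by their chromosomes.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <queue>
#include <unordered_set>
#include <algorithm>
#include <cstdlib>

using namespace Rcpp;

struct Chrom {
  std::vector<int> seq; // signed instance ids
  bool circular;
};

typedef std::vector<Chrom> State;

static int N0;                    // initial marker count
static std::vector<int> partner0; // 1-based, 0 = singular (size N0+1)

static inline int partner_of(int id) {
  if (id <= N0) {
    int p = partner0[id];
    if (p > 0) return p;
    return id + N0; // inserted homolog, if present
  }
  return id - N0;
}

// extremities: tail(i) = 2i, head(i) = 2i+1
static inline int tail(int i) { return 2 * i; }
static inline int head(int i) { return 2 * i + 1; }
static inline int pext(int e) {
  int i = e / 2;
  int p = partner_of(i);
  return 2 * p + (e & 1);
}

struct Graph {
  std::vector<int> adj;      // adjacency partner extremity, -1 none
  std::vector<char> present; // per id
  int maxid;
};

static void build_graph(const State &st, Graph &g) {
  int mx = 2 * N0;
  g.maxid = mx;
  g.adj.assign(2 * (mx + 1), -1);
  g.present.assign(mx + 1, 0);
  for (const Chrom &c : st) {
    int n = (int)c.seq.size();
    for (int j = 0; j < n; ++j) g.present[std::abs(c.seq[j])] = 1;
    for (int j = 0; j + 1 < n; ++j) {
      int a = c.seq[j] > 0 ? head(c.seq[j]) : tail(-c.seq[j]);
      int b = c.seq[j + 1] > 0 ? tail(c.seq[j + 1]) : head(-c.seq[j + 1]);
      g.adj[a] = b; g.adj[b] = a;
    }
    if (c.circular) {
      int a = c.seq[n - 1] > 0 ? head(c.seq[n - 1]) : tail(-c.seq[n - 1]);
      int b = c.seq[0] > 0 ? tail(c.seq[0]) : head(-c.seq[0]);
      g.adj[a] = b; g.adj[b] = a;
    }
  }
}

// rebuild chromosomes from an adjacency map and presence flags
static State rebuild(const Graph &g) {
  State st;
  std::vector<char> seen(2 * (g.maxid + 1), 0);
  for (int id = 1; id <= g.maxid; ++id) {
    if (!g.present[id]) { seen[tail(id)] = seen[head(id)] = 1; }
  }
  // linear chromosomes from telomeres
  for (int e = 0; e < (int)g.adj.size(); ++e) {
    if (seen[e] || g.adj[e] != -1) continue;
    Chrom c; c.circular = false;
    int cur = e;
    while (true) {
      int i = cur / 2;
      c.seq.push_back((cur & 1) ? -i : i); // entered at tail (even) => forward
      seen[cur] = 1;
      int other = cur ^ 1;
      seen[other] = 1;
      int nxt = g.adj[other];
      if (nxt == -1 || seen[nxt]) break;
      cur = nxt;
    }
    st.push_back(c);
  }
  // circular chromosomes
  for (int e = 0; e < (int)g.adj.size(); ++e) {
    if (seen[e]) continue;
    Chrom c; c.circular = true;
    int cur = e;
    while (!seen[cur]) {
      int i = cur / 2;
      c.seq.push_back((cur & 1) ? -i : i);
      seen[cur] = 1;
      int other = cur ^ 1;
      seen[other] = 1;
      int nxt = g.adj[other];
      if (nxt == -1) break;
      cur = nxt;
    }
    st.push_back(c);
  }
  return st;
}

static std::vector<int> flip_seq(const std::vector<int> &v) {
  std::vector<int> r(v.rbegin(), v.rend());
  for (int &x : r) x = -x;
  return r;
}

static std::string seq_key(const std::vector<int> &v, bool circular) {
  std::string s = circular ? "c" : "l";
  for (int x : v) { s += std::to_string(x); s += ","; }
  return s;
}

static std::string canon_key(const State &st) {
  std::vector<std::string> keys;
  for (const Chrom &c : st) {
    std::string best;
    if (!c.circular) {
      std::string k1 = seq_key(c.seq, false), k2 = seq_key(flip_seq(c.seq), false);
      best = std::min(k1, k2);
    } else {
      int n = (int)c.seq.size();
      std::vector<int> f = flip_seq(c.seq);
      for (int r = 0; r < n; ++r) {
        std::vector<int> a(c.seq.begin() + r, c.seq.end());
        a.insert(a.end(), c.seq.begin(), c.seq.begin() + r);
        std::string k = seq_key(a, true);
        if (best.empty() || k < best) best = k;
        std::vector<int> b(f.begin() + r, f.end());
        b.insert(b.end(), f.begin(), f.begin() + r);
        k = seq_key(b, true);
        if (k < best) best = k;
      }
    }
    keys.push_back(best);
  }
  std::sort(keys.begin(), keys.end());
  std::string out;
  for (const std::string &k : keys) { out += k; out += "|"; }
  return out;
}

static bool is_sd_state(const State &st) {
  Graph g;
  build_graph(st, g);
  for (int id = 1; id <= g.maxid; ++id) {
    if (!g.present[id]) continue;
    int p = partner_of(id);
    if (p > g.maxid || !g.present[p]) return false;
  }
  for (int e = 0; e < (int)g.adj.size(); ++e) {
    int a = g.adj[e];
    if (a < e) continue; // each adjacency once, skip none (-1)
    int pe = pext(e), pa = pext(a);
    if (g.adj[pe] != pa) return false;
    if (pe == e && pa == a) return false;
    if (pe == a && pa == e) return false;
  }
  return true;
}

static inline bool is_singular_present(int id) {
  // singular under the current matching: original marker without partner and
  // without an inserted homolog is handled by the caller via presence checks
  return id <= N0 && partner0[id] == 0;
}

static bool g_allow_ins = true;

static void successors(const State &st, std::vector<State> &out) {
  Graph g;
  build_graph(st, g);
  // collect sites: adjacencies (a < b) and telomeres of present markers
  std::vector<std::pair<int,int> > adjs;
  std::vector<int> telos;
  for (int id = 1; id <= g.maxid; ++id) {
    if (!g.present[id]) continue;
    for (int e : {tail(id), head(id)}) {
      int a = g.adj[e];
      if (a == -1) telos.push_back(e);
      else if (a > e) adjs.push_back(std::make_pair(e, a));
    }
  }
  std::vector<std::pair<int,int> > sites;
  for (auto &p : adjs) sites.push_back(p);
  for (int t : telos) sites.push_back(std::make_pair(t, -1));
  int ns = (int)sites.size();
  Graph h;
  // DCJ on two sites
  for (int i = 0; i < ns; ++i) {
    for (int j = i + 1; j < ns; ++j) {
      int a = sites[i].first, b = sites[i].second;
      int c = sites[j].first, d = sites[j].second;
      if (b != -1 && d != -1) {
        for (int variant = 0; variant < 2; ++variant) {
          h = g;
          h.adj[a] = h.adj[b] = h.adj[c] = h.adj[d] = -1;
          if (variant == 0) { h.adj[a] = c; h.adj[c] = a; h.adj[b] = d; h.adj[d] = b; }
          else { h.adj[a] = d; h.adj[d] = a; h.adj[b] = c; h.adj[c] = b; }
          out.push_back(rebuild(h));
        }
      } else if (b != -1 && d == -1) {
        for (int variant = 0; variant < 2; ++variant) {
          h = g;
          h.adj[a] = h.adj[b] = -1;
          int keep = variant == 0 ? a : b;
          h.adj[keep] = c; h.adj[c] = keep;
          out.push_back(rebuild(h));
        }
      } else if (b == -1 && d != -1) {
        for (int variant = 0; variant < 2; ++variant) {
          h = g;
          h.adj[c] = h.adj[d] = -1;
          int keep = variant == 0 ? c : d;
          h.adj[keep] = a; h.adj[a] = keep;
          out.push_back(rebuild(h));
        }
      } else {
        h = g;
        h.adj[a] = c; h.adj[c] = a;
        out.push_back(rebuild(h));
      }
    }
  }
  // single-site cut: ab -> a, b
  for (auto &p : adjs) {
    h = g;
    h.adj[p.first] = -1; h.adj[p.second] = -1;
    out.push_back(rebuild(h));
  }
  // deletions: contiguous singular sub-segments
  for (const Chrom &c : st) {
    int n = (int)c.seq.size();
    std::vector<int> sing(n);
    bool all_sing = true;
    for (int j = 0; j < n; ++j) {
      int id = std::abs(c.seq[j]);
      bool s = is_singular_present(id) && !(id <= N0 && g.present[id] == 1 &&
                id + N0 <= g.maxid && g.present[id + N0]);
      // a marker whose homolog has been inserted counts as matched
      sing[j] = s ? 1 : 0;
      if (!s) all_sing = false;
    }
    if (c.circular && all_sing) {
      State ns2;
      for (const Chrom &o : st) if (&o != &c) ns2.push_back(o);
      out.push_back(ns2); // whole circular singleton in one deletion
    }
    // runs of singular markers (with wrap on circular chromosomes)
    for (int start = 0; start < n; ++start) {
      if (!sing[start]) continue;
      if (c.circular) {
        for (int len = 1; len < n; ++len) {
          bool ok = true;
          for (int t = 0; t < len; ++t) if (!sing[(start + t) % n]) { ok = false; break; }
          if (!ok) break;
          Chrom rc; rc.circular = true;
          for (int t = 0; t < n - len; ++t) rc.seq.push_back(c.seq[(start + len + t) % n]);
          State ns2;
          for (const Chrom &o : st) if (&o != &c) ns2.push_back(o);
          if (!rc.seq.empty()) ns2.push_back(rc);
          out.push_back(ns2);
        }
      } else {
        for (int len = 1; start + len <= n; ++len) {
          if (!sing[start + len - 1]) break;
          Chrom left, right;
          left.circular = right.circular = false;
          for (int t = 0; t < start; ++t) left.seq.push_back(c.seq[t]);
          for (int t = start + len; t < n; ++t) left.seq.push_back(c.seq[t]);
          State ns2;
          for (const Chrom &o : st) if (&o != &c) ns2.push_back(o);
          if (!left.seq.empty()) ns2.push_back(left);
          out.push_back(ns2);
        }
      }
    }
  }
  // insertions: the single missing homolog of a singular present marker
  if (!g_allow_ins) return;
  for (int id = 1; id <= N0; ++id) {
    if (partner0[id] != 0 || !g.present[id]) continue;
    if (g.present[id + N0]) continue;
    int nid = id + N0;
    // new linear / circular chromosome
    for (int circ = 0; circ < 2; ++circ) {
      State ns2 = st;
      Chrom c; c.circular = circ == 1; c.seq.push_back(nid);
      ns2.push_back(c);
      out.push_back(ns2);
    }
    // into each adjacency (two orientations)
    for (auto &p : adjs) {
      for (int variant = 0; variant < 2; ++variant) {
        h = g;
        h.present[nid] = 1;
        int first = variant == 0 ? tail(nid) : head(nid);
        int last = variant == 0 ? head(nid) : tail(nid);
        h.adj[p.first] = first; h.adj[first] = p.first;
        h.adj[p.second] = last; h.adj[last] = p.second;
        out.push_back(rebuild(h));
      }
    }
    // at each telomere (two orientations)
    for (int t : telos) {
      for (int variant = 0; variant < 2; ++variant) {
        h = g;
        h.present[nid] = 1;
        int first = variant == 0 ? tail(nid) : head(nid);
        h.adj[t] = first; h.adj[first] = t;
        out.push_back(rebuild(h));
      }
    }
  }
}

// [[Rcpp::export]]
int oracle_bfs_cpp(List chroms, LogicalVector circular, IntegerVector partner,
                   int max_depth, bool allow_insertions) {
  N0 = (int)partner.size();
  g_allow_ins = allow_insertions;
  partner0.assign(N0 + 1, 0);
  for (int i = 0; i < N0; ++i) partner0[i + 1] = partner[i];
  State start;
  for (int k = 0; k < chroms.size(); ++k) {
    IntegerVector v = chroms[k];
    Chrom c;
    c.circular = circular[k];
    for (int j = 0; j < v.size(); ++j) c.seq.push_back(v[j]);
    start.push_back(c);
  }
  if (is_sd_state(start)) return 0;
  std::unordered_set<std::string> visited;
  std::vector<State> frontier;
  frontier.push_back(start);
  visited.insert(canon_key(start));
  for (int depth = 1; depth <= max_depth; ++depth) {
    std::vector<State> nxt;
    for (const State &s : frontier) {
      std::vector<State> succ;
      successors(s, succ);
      for (State &t : succ) {
        std::string key = canon_key(t);
        if (visited.count(key)) continue;
        visited.insert(key);
        if (is_sd_state(t)) return depth;
        nxt.push_back(std::move(t));
      }
      if ((visited.size() & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
    frontier.swap(nxt);
    if (frontier.empty()) break;
  }
  return -1;
}
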