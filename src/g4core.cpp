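#include <Rcpp.h>
#include <string>
#include <vector>
#include <array>
#include <cstdint>
using namespace Rcpp;

// Maximal runs of `base` (length >= min_run) chained while inter-run gaps
// stay within [1, max_gap].  Returns one row per maximal chain (block):
// start, end (0-based half-open), k (number of runs in the chain).
static void find_blocks(const std::string &s, char base, int min_run,
                        int max_gap, std::vector<int> &bs,
                        std::vector<int> &be, std::vector<int> &bk) {
  const int n = (int)s.size();
  // locate maximal runs
  std::vector<int> rs, re;
  int i = 0;
  while (i < n) {
    if (s[i] == base) {
      int j = i;
      while (j < n && s[j] == base) ++j;
      if (j - i >= min_run) { rs.push_back(i); re.push_back(j); }
      i = j;
    } else ++i;
  }
  const int m = (int)rs.size();
  int a = 0;
  while (a < m) {
    int b = a;
    while (b + 1 < m) {
      int gap = rs[b + 1] - re[b];
      if (gap >= 1 && gap <= max_gap) ++b; else break;
    }
    bs.push_back(rs[a]);
    be.push_back(re[b]);
    bk.push_back(b - a + 1);
    a = b + 1;
  }
}

// [[Rcpp::export]]
DataFrame run_blocks_cpp(std::string seq, char base = 'G', int min_run = 3,
                         int max_gap = 7) {
  std::vector<int> bs, be, bk;
  find_blocks(seq, base, min_run, max_gap, bs, be, bk);
  return DataFrame::create(_["start"] = bs, _["end"] = be, _["k"] = bk);
}

static int count_g4_one(const std::string &s, char base, int min_runs) {
  std::vector<int> bs, be, bk;
  find_blocks(s, base, 3, 7, bs, be, bk);
  int c = 0;
  for (size_t i = 0; i < bk.size(); ++i) if (bk[i] >= min_runs) ++c;
  return c;
}

// [[Rcpp::export]]
int count_g4_cpp(std::string seq, bool both_strands = true,
                 int min_runs = 4) {
  int c = count_g4_one(seq, 'G', min_runs);
  if (both_strands) c += count_g4_one(seq, 'C', min_runs);
  return c;
}

static int ridx(int k) {            // uniform integer in [0, k)
  int r;
  do { r = (int)(unif_rand() * k); } while (r >= k);
  return r;
}

// Altschul-Erickson exact dinucleotide shuffle (Eulerian path).
// Preserves the dinucleotide multiset and the first (hence last) character.
static std::string dinuc_shuffle_one(const std::string &s) {
  const int n = (int)s.size();
  if (n < 2) return s;
  // map characters to compact vertex ids
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  std::vector<char> sym;
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) {
    unsigned char c = (unsigned char)s[i];
    if (code[c] < 0) { code[c] = (int)sym.size(); sym.push_back(s[i]); }
    v[i] = code[c];
  }
  const int V = (int)sym.size();
  if (V == 1) return s;
  std::vector< std::vector<int> > adj(V);
  for (int i = 0; i + 1 < n; ++i) adj[v[i]].push_back(v[i + 1]);
  const int vlast = v[n - 1];
  // choose, for every non-terminal vertex with out-edges, a last-exit edge
  // such that last edges form a tree rooted at vlast; rejection-sample
  std::vector<int> last(V, -1);
  for (int tries = 0; ; ++tries) {
    for (int u = 0; u < V; ++u) {
      last[u] = -1;
      if (u != vlast && !adj[u].empty())
        last[u] = adj[u][ridx((int)adj[u].size())];
    }
    bool ok = true;
    for (int u = 0; u < V && ok; ++u) {
      if (u == vlast || adj[u].empty()) continue;
      int w = u, steps = 0;
      bool reach = false;
      while (steps <= V) {
        if (w == vlast) { reach = true; break; }
        w = last[w];
        if (w < 0) break;
        ++steps;
      }
      if (!reach) ok = false;
    }
    if (ok) break;
    if (tries > 10000) return s; // degenerate graph; give up, keep input
  }
  // shuffle remaining edges per vertex, append the reserved last edge
  std::vector< std::vector<int> > out(V);
  for (int u = 0; u < V; ++u) {
    std::vector<int> e = adj[u];
    if (last[u] >= 0) {
      // remove one instance of last[u]
      for (size_t i = 0; i < e.size(); ++i)
        if (e[i] == last[u]) { e.erase(e.begin() + i); break; }
    }
    for (int i = (int)e.size() - 1; i > 0; --i)
      std::swap(e[i], e[ridx(i + 1)]);
    if (last[u] >= 0) e.push_back(last[u]);
    out[u] = e;
  }
  // walk
  std::string res;
  res.reserve(n);
  std::vector<size_t> ptr(V, 0);
  int u = v[0];
  res.push_back(sym[u]);
  for (int i = 0; i + 1 < n; ++i) {
    int w = out[u][ptr[u]++];
    res.push_back(sym[w]);
    u = w;
  }
  return res;
}

// [[Rcpp::export]]
std::string dinuc_shuffle_cpp(std::string seq) {
  return dinuc_shuffle_one(seq);
}

// xoshiro-style fast PRNG, seeded from R's RNG for reproducibility
struct FastRng {
  uint64_t s;
  explicit FastRng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {            // splitmix64
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int below(int k) { return (int)(next() % (uint64_t)k); }
};

// streaming block counter: runs of >=3 of one base chained by 1-7 nt gaps
struct BlockCounter {
  int run, gap, k;
  bool active;
  int min_runs, hits;
  void reset(int mr) { run = gap = k = 0; active = false; min_runs = mr;
                       hits = 0; }
  void close_run() {
    if (active && gap >= 1 && gap <= 7) ++k;
    else { if (active && k >= min_runs) ++hits; k = 1; }
    active = true;
    gap = 0;
  }
  void feed(bool is_base) {
    if (is_base) { ++run; return; }
    if (run >= 3) close_run(); else gap += run;
    run = 0;
    ++gap;
  }
  int finish() {
    if (run >= 3) close_run(); else gap += run;
    run = 0;
    if (active && k >= min_runs) ++hits;
    int h = hits;
    active = false; k = 0; gap = 0; hits = 0;
    return h;
  }
};

// One permutation = independently shuffle every window (exact dinucleotide
// shuffle), count consensus motif blocks on the requested strands, sum.
// Per-window transition graphs are built once; per-permutation work uses
// preallocated buffers and a fast PRNG seeded from R's RNG stream.
// [[Rcpp::export]]
IntegerVector permute_counts_cpp(std::vector<std::string> windows, int n_perm,
                                 bool both_strands = true, int min_runs = 4) {
  const int W = (int)windows.size();
  // encode windows and build edge lists
  std::vector< std::vector<int> > enc(W);
  std::vector< std::array<std::vector<int>, 8> > graph(W);
  std::vector<int> gidx(W), cidx(W), v0(W), vlastv(W), nvert(W);
  for (int w = 0; w < W; ++w) {
    const std::string &s = windows[w];
    int code[256];
    for (int i = 0; i < 256; ++i) code[i] = -1;
    int nv = 0;
    std::vector<int> &v = enc[w];
    v.resize(s.size());
    gidx[w] = cidx[w] = -1;
    for (size_t i = 0; i < s.size(); ++i) {
      unsigned char c = (unsigned char)s[i];
      if (code[c] < 0) {
        code[c] = nv++;
        if (s[i] == 'G') gidx[w] = code[c];
        if (s[i] == 'C') cidx[w] = code[c];
      }
      v[i] = code[c];
    }
    nvert[w] = nv;
    if (s.size() >= 2) {
      for (size_t i = 0; i + 1 < s.size(); ++i)
        graph[w][v[i]].push_back(v[i + 1]);
    }
    v0[w] = v.empty() ? 0 : v[0];
    vlastv[w] = v.empty() ? 0 : v[v.size() - 1];
  }
  FastRng rng((uint64_t)(unif_rand() * 9007199254740992.0) + 1ULL);
  IntegerVector out(n_perm);
  std::array<std::vector<int>, 8> work;
  std::vector<int> ptr(8), last(8);
  BlockCounter bcG, bcC;
  for (int p = 0; p < n_perm; ++p) {
    long tot = 0;
    for (int w = 0; w < W; ++w) {
      const int n = (int)enc[w].size();
      const int nv = nvert[w];
      const int vl = vlastv[w];
      if (n < 2 || nv == 1) {
        // fixed sequence; count directly
        bcG.reset(min_runs); bcC.reset(min_runs);
        for (int i = 0; i < n; ++i) {
          bcG.feed(enc[w][i] == gidx[w]);
          bcC.feed(enc[w][i] == cidx[w]);
        }
        tot += bcG.finish();
        if (both_strands) tot += bcC.finish(); else bcC.finish();
        continue;
      }
      for (int u = 0; u < nv; ++u) work[u] = graph[w][u];
      // sample last-exit edges forming a tree into vl
      for (int tries = 0; ; ++tries) {
        bool ok = true;
        for (int u = 0; u < nv; ++u) {
          last[u] = -1;
          if (u != vl && !work[u].empty())
            last[u] = work[u][rng.below((int)work[u].size())];
        }
        for (int u = 0; u < nv && ok; ++u) {
          if (u == vl || work[u].empty()) continue;
          int x = u, steps = 0;
          bool reach = false;
          while (steps <= nv) {
            if (x == vl) { reach = true; break; }
            x = last[x];
            if (x < 0) break;
            ++steps;
          }
          if (!reach) ok = false;
        }
        if (ok) break;
        if (tries > 10000) break;
      }
      // move one instance of the reserved edge to the back, shuffle the rest
      for (int u = 0; u < nv; ++u) {
        std::vector<int> &e = work[u];
        int m = (int)e.size();
        if (last[u] >= 0) {
          for (int i = 0; i < m; ++i)
            if (e[i] == last[u]) { std::swap(e[i], e[m - 1]); break; }
          --m;  // keep reserved edge fixed at the back
        }
        for (int i = m - 1; i > 0; --i)
          std::swap(e[i], e[rng.below(i + 1)]);
        ptr[u] = 0;
      }
      // walk and count
      bcG.reset(min_runs); bcC.reset(min_runs);
      int u = v0[w];
      bcG.feed(u == gidx[w]);
      bcC.feed(u == cidx[w]);
      for (int i = 0; i + 1 < n; ++i) {
        int x = work[u][ptr[u]++];
        bcG.feed(x == gidx[w]);
        bcC.feed(x == cidx[w]);
        u = x;
      }
      tot += bcG.finish();
      if (both_strands) tot += bcC.finish(); else bcC.finish();
    }
    out[p] = (int)tot;
    if ((p & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// First-order Markov chain over A,C,G,T given a 4x4 transition matrix
// (rows = from, order A,C,G,T) and initial distribution.
// [[Rcpp::export]]
std::string markov_seq_cpp(int n, NumericMatrix trans, NumericVector init) {
  static const char B[4] = {'A', 'C', 'G', 'T'};
  std::string s(n, 'A');
  if (n == 0) return s;
  // cumulative rows
  double cinit[4], ctr[4][4];
  double acc = 0;
  for (int j = 0; j < 4; ++j) { acc += init[j]; cinit[j] = acc; }
  for (int i = 0; i < 4; ++i) {
    acc = 0;
    for (int j = 0; j < 4; ++j) { acc += trans(i, j); ctr[i][j] = acc; }
  }
  double u = unif_rand() * cinit[3];
  int st = 0;
  while (st < 3 && u > cinit[st]) ++st;
  s[0] = B[st];
  for (int i = 1; i < n; ++i) {
    u = unif_rand() * ctr[st][3];
    int nx = 0;
    while (nx < 3 && u > ctr[st][nx]) ++nx;
    s[i] = B[nx];
    st = nx;
  }
  return s;
}
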