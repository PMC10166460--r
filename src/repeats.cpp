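#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Exhaustive maximal ungapped repeat-pair scan.
//
// A candidate pair is a window of length len >= min_len on a (anti)diagonal
// of the self-comparison matrix, with identity = matches/len >= min_identity
// and, for direct repeats, non-overlapping arms (len <= diagonal offset).
// A pair is reported iff it is single-step inextensible: neither extending
// by one position on the left end nor on the right end yields another
// structurally valid window with identity >= the threshold. Identity
// comparisons use exact integer arithmetic (threshold scaled by 1e6).
//
// N residues never match anything, including N.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

struct Hit { int a1, a2, len, matches; };

// Scan one diagonal given its match vector m[0..T-1].
// Positions t map to arm1 start offset; cap is the maximum admissible
// window length for structural reasons (arm overlap for direct repeats),
// max_arm bounds the reported/extended length.
static void scan_vector(const std::vector<uint8_t> &m,
                        int min_len, int64_t num, int64_t den,
                        int cap, int max_arm,
                        std::vector<Hit> &hits, int d_or_c, bool direct) {
  const int T = (int)m.size();
  if (T < min_len) return;
  std::vector<int64_t> C(T + 1), Mc(T + 1);
  C[0] = 0; Mc[0] = 0;
  const int64_t up = den - num;   // score step on a match
  for (int t = 0; t < T; ++t) {
    C[t + 1] = C[t] + (m[t] ? up : -num);
    Mc[t + 1] = Mc[t] + (m[t] ? 1 : 0);
  }
  const int len_cap = std::min(cap, max_arm);
  if (len_cap < min_len) return;
  for (int a = 0; a + min_len <= T; ++a) {
    int bmax = std::min(T - 1, a + len_cap - 1);
    for (int b = a + min_len - 1; b <= bmax; ++b) {
      int len = b - a + 1;
      // prune: even matching every remaining position cannot reach 0
      if (C[b + 1] - C[a] + (int64_t)(bmax - b) * up < 0) break;
      if (C[b + 1] - C[a] < 0) continue;
      bool left_blocked = (a == 0) || (len + 1 > len_cap) ||
                          (C[b + 1] - C[a - 1] < 0);
      bool right_blocked = (b == T - 1) || (len + 1 > len_cap) ||
                           (C[b + 2] - C[a] < 0);
      if (left_blocked && right_blocked) {
        Hit h;
        h.a1 = a;
        h.len = len;
        h.matches = (int)(Mc[b + 1] - Mc[a]);
        if (direct) {
          h.a2 = a + d_or_c;            // arm2 start offset
        } else {
          h.a2 = d_or_c - b;            // arm2 start = c - b
        }
        hits.push_back(h);
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".repeat_scan_cpp")]]
DataFrame repeat_scan_cpp(std::string s, bool direct,
                          int min_len, double min_identity, int max_arm) {
  const int L = (int)s.size();
  std::vector<Hit> hits;
  const int64_t den = 1000000LL;
  const int64_t num = (int64_t)std::llround(min_identity * (double)den);
  if (direct) {
    // diagonal d = arm2_start - arm1_start; non-overlap requires len <= d
    for (int d = min_len; d <= L - min_len; ++d) {
      const int T = L - d;
      std::vector<uint8_t> m(T);
      for (int t = 0; t < T; ++t) {
        char x = s[t], y = s[t + d];
        m[t] = (x == y && x != 'N') ? 1 : 0;
      }
      scan_vector(m, min_len, num, den, d, max_arm, hits, d, true);
    }
  } else {
    // anti-diagonal c = i + j over pairings (i, c - i); windows live on
    // i in [i0, i1] with i1 < c/2 so arm2 starts strictly after arm1 ends
    for (int c = 2 * min_len - 1; c <= 2 * L - 3; ++c) {
      int i0 = std::max(0, c - (L - 1));
      int i1 = (c - 1) / 2;
      if (i1 - i0 + 1 < min_len) continue;
      const int T = i1 - i0 + 1;
      std::vector<uint8_t> m(T);
      for (int t = 0; t < T; ++t) {
        int i = i0 + t, j = c - i;
        char x = s[i], y = s[j];
        m[t] = (x != 'N' && y != 'N' && x == comp_base(y)) ? 1 : 0;
      }
      // windows [a,b] in t-space; arm1 = [i0+a, i0+b], arm2 = [c-(i0+b), c-(i0+a)]
      std::vector<Hit> local;
      scan_vector(m, min_len, num, den, T, max_arm, local, 0, true);
      for (auto &h : local) {
        int a1 = i0 + h.a1;
        int b1 = a1 + h.len - 1;
        Hit g;
        g.a1 = a1;
        g.a2 = c - b1;  // arm2 start
        g.len = h.len;
        g.matches = h.matches;
        hits.push_back(g);
      }
    }
  }
  int n = (int)hits.size();
  IntegerVector a1(n), a2(n), len(n), matches(n);
  for (int i = 0; i < n; ++i) {
    a1[i] = hits[i].a1 + 1;  // 1-based within the scanned string
    a2[i] = hits[i].a2 + 1;
    len[i] = hits[i].len;
    matches[i] = hits[i].matches;
  }
  return DataFrame::create(_["arm1_start"] = a1, _["arm2_start"] = a2,
                           _["length"] = len, _["matches"] = matches);
}
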