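#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Intermolecular DNA duplex minimum free energy under a nearest-neighbor
// stack model with an affine interior loop/bulge penalty.
//
// Strand a pairs antiparallel with strand b; equivalently we align a
// against R = reverse complement of b, where a matched column means a
// Watson-Crick pair. Consecutive matched columns contribute the stack
// increment dG(a[i], a[i+1]) (the paired bases are determined by
// complementarity); a loop skipping g bases in total costs
// loop_open + loop_extend * g; the duplex pays one initiation penalty and
// a terminal penalty for each terminal A:T pair. If no pairing achieves
// dG < 0 the reported energy is 0 (no stable duplex).

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static double duplex_impl(const std::string &a, const std::string &bR,
                          const double *stack /*4x4 row=first base of dimer*/,
                          double init_dG, double term_at,
                          double loop_open, double loop_ext) {
  const int n = (int)a.size(), m = (int)bR.size();
  const double INF = std::numeric_limits<double>::infinity();
  // M[i][j]: min energy (stacks+loops+start terminal) of a duplex whose
  // last pair is (a[i], bR[j]); D: best M[i'][j'] + loop_ext per skipped base
  std::vector<double> M(m), D(m), Mp(m), Dp(m);
  double best = INF;
  for (int j = 0; j < m; ++j) { Mp[j] = INF; Dp[j] = INF; }
  for (int i = 0; i < n; ++i) {
    int ai = base_idx(a[i]);
    for (int j = 0; j < m; ++j) {
      bool pairable = ai >= 0 && a[i] == bR[j];
      double Mij = INF;
      if (pairable) {
        double start = (a[i] == 'A' || a[i] == 'T') ? term_at : 0.0;
        Mij = start;
        if (i > 0 && j > 0) {
          int ap = base_idx(a[i - 1]);
          if (Mp[j - 1] < INF && ap >= 0 && a[i - 1] == bR[j - 1]) {
            double st = Mp[j - 1] + stack[ap * 4 + ai];
            if (st < Mij) Mij = st;
          }
          if (Dp[j - 1] < INF) {
            double lp = Dp[j - 1] + loop_open;
            if (lp < Mij) Mij = lp;
          }
        }
        double end = (a[i] == 'A' || a[i] == 'T') ? term_at : 0.0;
        double total = Mij + end + init_dG;
        if (total < best) best = total;
      }
      M[j] = Mij;
      // D[i][j] = min over i'<=i, j'<=j of M[i'][j'] + loop_ext*((i-i')+(j-j'))
      double d = M[j];
      if (j > 0 && D[j - 1] < INF) d = std::min(d, D[j - 1] + loop_ext);
      if (Dp[j] < INF) d = std::min(d, Dp[j] + loop_ext);
      D[j] = d;
    }
    std::swap(M, Mp); std::swap(D, Dp);
  }
  if (best >= 0.0 || best == INF) return 0.0;
  return best;
}

//' @noRd
// [[Rcpp::export(name = ".duplex_energy_cpp")]]
double duplex_energy_cpp(std::string a, std::string b,
                         NumericMatrix stack_dG,
                         double init_dG, double term_at,
                         double loop_open, double loop_ext) {
  std::string bR(b.rbegin(), b.rend());
  for (auto &c : bR) c = comp_base(c);
  std::vector<double> st(16);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) st[i * 4 + j] = stack_dG(i, j);
  return duplex_impl(a, bR, st.data(), init_dG, term_at, loop_open, loop_ext);
}

//' @noRd
// [[Rcpp::export(name = ".duplex_matrix_cpp")]]
NumericMatrix duplex_matrix_cpp(CharacterVector windows,
                                NumericMatrix stack_dG,
                                double init_dG, double term_at,
                                double loop_open, double loop_ext) {
  int n = windows.size();
  std::vector<double> st(16);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) st[i * 4 + j] = stack_dG(i, j);
  std::vector<std::string> w(n), wR(n);
  for (int i = 0; i < n; ++i) {
    w[i] = as<std::string>(windows[i]);
    std::string r(w[i].rbegin(), w[i].rend());
    for (auto &c : r) c = comp_base(c);
    wR[i] = r;
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double e = duplex_impl(w[i], wR[j], st.data(), init_dG, term_at,
                             loop_open, loop_ext);
      out(i, j) = e;
      out(j, i) = e;
    }
  }
  return out;
}
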