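#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap global alignment, score only.
// Gap of length L costs gap_open + gap_extend * L (open charged once, every
// gapped residue including the first also pays extend). With
// end_gaps_free the leading/trailing gaps on either sequence cost nothing
// (EMBOSS Needle default, endweight = false).
static double nw_score_impl(const std::string &a, const std::string &b,
                            double match, double mismatch,
                            double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // rows over a (i), columns over b (j)
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  // X: gap in b (consume a), Y: gap in a (consume b)
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -(gap_open + gap_extend * j);
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG; Y[0] = NEG;
    X[0] = -(gap_open + gap_extend * i);
    for (int j = 1; j <= m; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      bool is_match = (ca == cb) && ca != 'N';
      double s = is_match ? match : mismatch;
      double diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      M[j] = (diag == NEG) ? NEG : diag + s;
      double xo = std::max(Mp[j], Yp[j]) - (gap_open + gap_extend);
      double xe = Xp[j] - gap_extend;
      X[j] = std::max(xo, xe);
      double yo = std::max(M[j - 1], X[j - 1]) - (gap_open + gap_extend);
      double ye = Y[j - 1] - gap_extend;
      Y[j] = std::max(yo, ye);
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// Free-end-gap variant needs row/column maxima of the match state; do the
// DP keeping them as we go.
static double nw_score_free(const std::string &a, const std::string &b,
                            double match, double mismatch,
                            double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = 0.0; Xp[0] = 0.0; Yp[0] = 0.0;
  for (int j = 1; j <= m; ++j) { Mp[j] = 0.0; Xp[j] = NEG; Yp[j] = 0.0; }
  double best = (n == 0 || m == 0) ? 0.0 : NEG;
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG; X[0] = 0.0; Y[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      bool is_match = (ca == cb) && ca != 'N';
      double s = is_match ? match : mismatch;
      // leading end gaps are free: any cell may start an alignment
      double diag = std::max(std::max(Mp[j - 1], Xp[j - 1]),
                             std::max(Yp[j - 1], 0.0));
      M[j] = diag + s;
      double xo = std::max(Mp[j], Yp[j]) - (gap_open + gap_extend);
      X[j] = std::max(xo, Xp[j] - gap_extend);
      double yo = std::max(M[j - 1], X[j - 1]) - (gap_open + gap_extend);
      Y[j] = std::max(yo, Y[j - 1] - gap_extend);
      // trailing end gaps free: alignment may end at any matched cell on
      // the boundary of the consumed region; equivalently best M over all
      // cells whose suffixes can be gapped out for free -- that is every
      // cell, because both trailing tails are end gaps.
      if (M[j] > best) best = M[j];
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  // With free end gaps the degenerate alignment that gaps out both whole
  // sequences scores 0; the reported optimum is never below that.
  return std::max(best, 0.0);
}

//' @noRd
// [[Rcpp::export(name = ".nw_score_cpp")]]
double nw_score_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    bool end_gaps_free) {
  if (end_gaps_free)
    return nw_score_free(a, b, match, mismatch, gap_open, gap_extend);
  return nw_score_impl(a, b, match, mismatch, gap_open, gap_extend);
}

//' @noRd
// [[Rcpp::export(name = ".nw_matrix_cpp")]]
NumericMatrix nw_matrix_cpp(CharacterVector windows,
                            double match, double mismatch,
                            double gap_open, double gap_extend,
                            bool end_gaps_free) {
  int n = windows.size();
  NumericMatrix out(n, n);
  std::vector<std::string> w(n);
  for (int i = 0; i < n; ++i) w[i] = as<std::string>(windows[i]);
  for (int i = 0; i < n; ++i) {
    out(i, i) = end_gaps_free
      ? nw_score_free(w[i], w[i], match, mismatch, gap_open, gap_extend)
      : nw_score_impl(w[i], w[i], match, mismatch, gap_open, gap_extend);
    for (int j = i + 1; j < n; ++j) {
      double s = end_gaps_free
        ? nw_score_free(w[i], w[j], match, mismatch, gap_open, gap_extend)
        : nw_score_impl(w[i], w[j], match, mismatch, gap_open, gap_extend);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}
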