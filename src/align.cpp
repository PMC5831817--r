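#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Local alignment score under affine gaps (Gotoh, linear space).
// a, b: 0-based residue indices into `sub`. A gap of length k costs
// gap_open + k * gap_extend.
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const int na = sub.nrow();
  const double ninf = -1e30;
  const double go = gap_open + gap_extend, ge = gap_extend;
  std::vector<double> smat(sub.begin(), sub.end()); // column-major
  std::vector<int> bi(b.begin(), b.end());
  std::vector<double> Hrow(m + 1, 0.0), Fcol(m + 1, ninf);
  double best = 0.0;
  double *H = Hrow.data(), *F = Fcol.data();
  const int *bp = bi.data();
  for (int i = 1; i <= n; ++i) {
    double Hdiag = 0.0;       // H[i-1][0]
    double Hleft = 0.0;       // H[i][0]
    double Erow = ninf;
    const double *srow = smat.data() + a[i - 1]; // + na*b[j-1] per column
    for (int j = 1; j <= m; ++j) {
      double e1 = Erow - ge, e2 = Hleft - go;
      Erow = e1 > e2 ? e1 : e2;
      double f1 = F[j] - ge, f2 = H[j] - go;
      double Fj = f1 > f2 ? f1 : f2;
      F[j] = Fj;
      double h = Hdiag + srow[na * bp[j - 1]];
      if (Erow > h) h = Erow;
      if (Fj > h) h = Fj;
      if (h < 0.0) h = 0.0;
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Global alignment maximising (matches - gap_cost * gaps); mismatches score 0.
// Returns c(matches, alignment_columns) from a deterministic traceback
// (preference diagonal > up > left on ties).
// [[Rcpp::export]]
IntegerVector nw_identity_cpp(IntegerVector a, IntegerVector b,
                              double gap_cost) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix T(n + 1, m + 1); // 0 diag, 1 up, 2 left
  for (int i = 1; i <= n; ++i) { S(i, 0) = -gap_cost * i; T(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = -gap_cost * j; T(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? 1.0 : 0.0);
      double up = S(i - 1, j) - gap_cost;
      double left = S(i, j - 1) - gap_cost;
      double bestv = diag; int t = 0;
      if (up > bestv) { bestv = up; t = 1; }
      if (left > bestv) { bestv = left; t = 2; }
      S(i, j) = bestv; T(i, j) = t;
    }
  }
  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    int t = T(i, j);
    if (t == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (t == 1) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  return IntegerVector::create(matches, cols);
}

// Sliding-window profile scores: window w (0-based start) gets
// sum over columns c of logodds(c, seq[w + c]). Returns numeric(0) when the
// sequence is shorter than the profile.
// [[Rcpp::export]]
NumericVector profile_window_scores_cpp(IntegerVector seq, NumericMatrix logodds) {
  const int L = logodds.nrow();
  const int n = seq.size();
  if (n < L) return NumericVector(0);
  const int nw = n - L + 1;
  NumericVector out(nw);
  for (int w = 0; w < nw; ++w) {
    double s = 0.0;
    for (int c = 0; c < L; ++c) s += logodds(c, seq[w + c]);
    out[w] = s;
  }
  return out;
}
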