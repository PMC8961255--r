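#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Draw m sequential NPI-B values into out, growing the ordered cut set after
// every draw (consecutive A(n), A(n+1), ... assumptions).  cuts holds
// L, x_(1), ..., x_(n), R and is modified in place.
static inline void npib_fill(std::vector<double>& cuts, double* out, int m) {
  for (int k = 0; k < m; ++k) {
    int nint = static_cast<int>(cuts.size()) - 1;
    int j = static_cast<int>(unif_rand() * nint);
    if (j >= nint) j = nint - 1;  // guard unif_rand() == 1.0
    double lo = cuts[j], hi = cuts[j + 1];
    double val = lo + unif_rand() * (hi - lo);
    out[k] = val;
    cuts.insert(std::upper_bound(cuts.begin(), cuts.end(), val), val);
  }
}

static std::vector<double> make_cuts(const NumericVector& xs, double L,
                                     double R, int m) {
  std::vector<double> cuts;
  cuts.reserve(xs.size() + m + 2);
  cuts.push_back(L);
  cuts.insert(cuts.end(), xs.begin(), xs.end());
  cuts.push_back(R);
  return cuts;
}

// [[Rcpp::export]]
NumericVector cpp_npib_sample(NumericVector xs, double L, double R, int m) {
  std::vector<double> cuts = make_cuts(xs, L, R, m);
  NumericVector out(m);
  if (m > 0) npib_fill(cuts, REAL(out), m);
  return out;
}

// N independent NPI-B future samples (one per row); the working set resets
// to the original data for every row.
// [[Rcpp::export]]
NumericMatrix cpp_npib_matrix(NumericVector xs, double L, double R, int m,
                              int N) {
  NumericMatrix out(N, m);
  std::vector<double> base = make_cuts(xs, L, R, m);
  std::vector<double> cuts;
  std::vector<double> row(m > 0 ? m : 1);
  for (int i = 0; i < N; ++i) {
    cuts = base;
    if (m > 0) npib_fill(cuts, row.data(), m);
    for (int k = 0; k < m; ++k) out(i, k) = row[k];
  }
  return out;
}

// Mann-Whitney U statistic per row pair: #{(a,b): X[i,a] > Y[i,b]},
// ties counted 1/2 (bootstrap rows are almost surely tie-free).
// [[Rcpp::export]]
NumericVector cpp_mwu_rows(NumericMatrix X, NumericMatrix Y) {
  int N = X.nrow(), n1 = X.ncol(), n2 = Y.ncol();
  if (Y.nrow() != N) stop("X and Y must have the same number of rows");
  NumericVector U(N);
  for (int i = 0; i < N; ++i) {
    double u = 0.0;
    for (int a = 0; a < n1; ++a) {
      double xa = X(i, a);
      for (int b = 0; b < n2; ++b) {
        double yb = Y(i, b);
        if (xa > yb) u += 1.0;
        else if (xa == yb) u += 0.5;
      }
    }
    U[i] = u;
  }
  return U;
}
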