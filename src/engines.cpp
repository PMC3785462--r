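#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Margin-fixed resampling of 2xk tables: given column totals c_j and row
// totals (n0, n1), the control row is drawn column by column from the
// conditional multivariate hypergeometric distribution — distributionally
// identical to Patefield's algorithm for two-row tables. Uses R's RNG, so
// set.seed() in R governs reproducibility.

// Draw the control-row counts into x (length k). colsum: column totals,
// n0: control row total, N: grand total.
static inline void draw_control_row(const std::vector<int>& colsum,
                                    int n0, int N, std::vector<int>& x) {
  int k = (int) colsum.size();
  int nrem = N, n0rem = n0;
  for (int j = 0; j < k - 1; j++) {
    int cj = colsum[j];
    // number of the cj column members falling in the control row
    int xj = (int) ::R::rhyper((double) n0rem, (double) (nrem - n0rem),
                               (double) cj);
    x[j] = xj;
    n0rem -= xj;
    nrem -= cj;
  }
  x[k - 1] = n0rem;
}

// Pearson chi-square statistic of the 2xk table with control row x,
// column totals colsum, expected control-row counts e0 (e1 = colsum - e0).
static inline double chisq_from_row(const std::vector<int>& x,
                                    const std::vector<int>& colsum,
                                    const std::vector<double>& e0,
                                    const std::vector<double>& e1) {
  double s = 0.0;
  int k = (int) x.size();
  for (int j = 0; j < k; j++) {
    double d0 = x[j] - e0[j];
    double d1 = (colsum[j] - x[j]) - e1[j];
    s += d0 * d0 / e0[j] + d1 * d1 / e1[j];
  }
  return s;
}

// Retain non-empty columns of table i (stored as columns of the k x n
// matrices X0, X1); fills colsum/x0 and returns row totals via n0/n1.
static int retain_columns(const IntegerMatrix& X0, const IntegerMatrix& X1,
                          int i, std::vector<int>& colsum,
                          std::vector<int>& x0, int& n0, int& n1) {
  int k = X0.nrow();
  colsum.clear(); x0.clear();
  n0 = 0; n1 = 0;
  for (int j = 0; j < k; j++) {
    int a = X0(j, i), b = X1(j, i);
    n0 += a; n1 += b;
    if (a + b > 0) { colsum.push_back(a + b); x0.push_back(a); }
  }
  return (int) colsum.size();
}

//' @name mc_engines
//' @title Batch Monte-Carlo p-value engines (internal)
//' @description Internal compiled kernels: for each 2xk table of a batch
//'   (columns of the k x n control/case count matrices), estimate the
//'   permutation or Fisher Monte-Carlo p-value from B margin-fixed
//'   resamples. Estimator: (1 + #extreme) / (B + 1).
//' When `early_alpha > 0`, resampling for a table stops as soon as the
//' accumulated extreme count guarantees the full-B p-value would be
//' `>= early_alpha`; the returned value is then only a lower bound that is
//' itself `>= early_alpha`, so every rejection indicator `p < a` with
//' `a <= early_alpha` is exactly the one the full-B run would give.
//' @param X0 integer matrix, k x n, control-row counts per table.
//' @param X1 integer matrix, k x n, case-row counts per table.
//' @param B number of margin-fixed resamples per table.
//' @param early_alpha early-termination threshold (0 disables it).
//' @return numeric vector of n p-values.
//' @keywords internal
// [[Rcpp::export]]
NumericVector perm_pvalues_cpp(IntegerMatrix X0, IntegerMatrix X1, int B,
                               double early_alpha = 0.0) {
  if (B < 1) stop("B must be >= 1");
  // not rejected at early_alpha once cnt >= early_alpha * (B+1) - 1
  double stop_at = early_alpha > 0 ? early_alpha * (B + 1.0) - 1.0 - 1e-9
                                   : 2.0 * B;
  int n = X0.ncol();
  NumericVector out(n);
  std::vector<int> colsum, x0, x;
  std::vector<double> e0, e1;
  for (int i = 0; i < n; i++) {
    int n0, n1;
    int kk = retain_columns(X0, X1, i, colsum, x0, n0, n1);
    if (n0 == 0 || n1 == 0) stop("degenerate table: a zero row sum");
    if (kk < 2) { out[i] = 1.0; continue; }  // single non-empty column
    int N = n0 + n1;
    e0.resize(kk); e1.resize(kk);
    for (int j = 0; j < kk; j++) {
      e0[j] = (double) colsum[j] * n0 / N;
      e1[j] = (double) colsum[j] * n1 / N;
    }
    double obs = chisq_from_row(x0, colsum, e0, e1);
    double thr = obs - 1e-7 * (obs > 1.0 ? obs : 1.0);
    x.resize(kk);
    int cnt = 0, b = 0;
    for (; b < B; b++) {
      if ((double) cnt >= stop_at) break;
      draw_control_row(colsum, n0, N, x);
      if (chisq_from_row(x, colsum, e0, e1) >= thr) cnt++;
    }
    out[i] = (1.0 + cnt) / (b + 1.0);
  }
  return out;
}

//' @rdname mc_engines
//' @keywords internal
// [[Rcpp::export]]
NumericVector fisher_pvalues_cpp(IntegerMatrix X0, IntegerMatrix X1, int B,
                                 double early_alpha = 0.0) {
  if (B < 1) stop("B must be >= 1");
  double stop_at = early_alpha > 0 ? early_alpha * (B + 1.0) - 1.0 - 1e-9
                                   : 2.0 * B;
  int n = X0.ncol();
  NumericVector out(n);
  std::vector<int> colsum, x0, x;
  for (int i = 0; i < n; i++) {
    int n0, n1;
    int kk = retain_columns(X0, X1, i, colsum, x0, n0, n1);
    if (n0 == 0 || n1 == 0) stop("degenerate table: a zero row sum");
    if (kk < 2) { out[i] = 1.0; continue; }
    int N = n0 + n1;
    // per-column lookup of log C(c_j, x): the table's conditional
    // log-probability is sum_j log C(c_j, x_j) minus a margin constant
    // that cancels in the comparison.
    std::vector< std::vector<double> > lut(kk);
    for (int j = 0; j < kk; j++) {
      int cj = colsum[j];
      lut[j].resize(cj + 1);
      for (int v = 0; v <= cj; v++)
        lut[j][v] = ::R::lchoose((double) cj, (double) v);
    }
    double obs = 0.0;
    for (int j = 0; j < kk; j++) obs += lut[j][x0[j]];
    double thr = obs + 1e-7;
    x.resize(kk);
    int cnt = 0, b = 0;
    for (; b < B; b++) {
      if ((double) cnt >= stop_at) break;
      draw_control_row(colsum, n0, N, x);
      double lp = 0.0;
      for (int j = 0; j < kk; j++) lp += lut[j][x[j]];
      if (lp <= thr) cnt++;
    }
    out[i] = (1.0 + cnt) / (b + 1.0);
  }
  return out;
}

//' @rdname mc_engines
//' @param table 2xk integer matrix.
//' @keywords internal
// [[Rcpp::export]]
List sample_margin_fixed_cpp(IntegerMatrix table, int B) {
  int k = table.ncol();
  std::vector<int> colsum(k), x(k);
  int n0 = 0, n1 = 0;
  for (int j = 0; j < k; j++) {
    colsum[j] = table(0, j) + table(1, j);
    n0 += table(0, j);
    n1 += table(1, j);
  }
  int N = n0 + n1;
  List out(B);
  for (int b = 0; b < B; b++) {
    draw_control_row(colsum, n0, N, x);
    IntegerMatrix t(2, k);
    for (int j = 0; j < k; j++) {
      t(0, j) = x[j];
      t(1, j) = colsum[j] - x[j];
    }
    out[b] = t;
  }
  return out;
}
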