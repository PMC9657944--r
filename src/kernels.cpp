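#include <Rcpp.h>
using namespace Rcpp;

// Gather rows of M at `gather` (1-based; empty = identity) and sum them into
// `ngroups` bins keyed by `groups`. The hot loop of graph message passing.
// [[Rcpp::export]]
NumericMatrix agg_rows_cpp(const NumericMatrix& M, const IntegerVector& gather,
                           const IntegerVector& groups, int ngroups) {
  const int d = M.ncol();
  const int mr = M.nrow();
  const int np = groups.size();
  const bool identity = gather.size() == 0;
  NumericMatrix out(ngroups, d);
  const int* gt = identity ? (const int*) nullptr : INTEGER(gather);
  const int* gr = INTEGER(groups);
  const double* m = REAL(M);
  double* o = REAL(out);
  for (int j = 0; j < d; ++j) {
    const double* mj = m + (size_t) j * mr;
    double* oj = o + (size_t) j * ngroups;
    if (identity) {
      for (int p = 0; p < np; ++p) oj[gr[p] - 1] += mj[p];
    } else {
      for (int p = 0; p < np; ++p) oj[gr[p] - 1] += mj[gt[p] - 1];
    }
  }
  return out;
}

// M + b recycled across rows
// [[Rcpp::export]]
NumericMatrix add_bias_cpp(const NumericMatrix& M, const NumericVector& b) {
  const int n = M.nrow(), d = M.ncol();
  NumericMatrix out(n, d);
  const double* m = REAL(M);
  const double* bb = REAL(b);
  double* o = REAL(out);
  for (int j = 0; j < d; ++j) {
    const double bj = bb[j];
    const double* mj = m + (size_t) j * n;
    double* oj = o + (size_t) j * n;
    for (int i = 0; i < n; ++i) oj[i] = mj[i] + bj;
  }
  return out;
}

// elementwise max(x, 0)
// [[Rcpp::export]]
NumericMatrix relu_cpp(const NumericMatrix& M) {
  const R_xlen_t n = M.size();
  NumericMatrix out(M.nrow(), M.ncol());
  const double* m = REAL(M);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = m[i] > 0 ? m[i] : 0;
  return out;
}

// D * (H > 0): gradient through a relu whose output was H
// [[Rcpp::export]]
NumericMatrix relu_bwd_cpp(const NumericMatrix& D, const NumericMatrix& H) {
  const R_xlen_t n = D.size();
  NumericMatrix out(D.nrow(), D.ncol());
  const double* d = REAL(D);
  const double* h = REAL(H);
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = h[i] > 0 ? d[i] : 0;
  return out;
}
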