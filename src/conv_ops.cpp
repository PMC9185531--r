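#include <Rcpp.h>
using namespace Rcpp;

// Gather im2col patches: out(r, c) = x[row_base[r] + col_base[c]].
// row_base/col_base are 0-based linear offsets into the padded input array.
// [[Rcpp::export]]
NumericMatrix im2col_gather(NumericVector x, IntegerVector row_base,
                            IntegerVector col_base) {
  const int nr = row_base.size(), nc = col_base.size();
  NumericMatrix out(nr, nc);
  const double *px = x.begin();
  double *po = out.begin();
  for (int c = 0; c < nc; ++c) {
    const int cb = col_base[c];
    const int *rb = row_base.begin();
    double *col = po + (R_xlen_t)c * nr;
    for (int r = 0; r < nr; ++r) col[r] = px[rb[r] + cb];
  }
  return out;
}

// Scatter-add the patch-gradient matrix back onto the padded input:
// dx[row_base[r] + col_base[c]] += dP(r, c).
// [[Rcpp::export]]
NumericVector col2im_scatter(NumericMatrix dP, int n, IntegerVector row_base,
                             IntegerVector col_base) {
  NumericVector dx(n);
  const int nr = row_base.size(), nc = col_base.size();
  double *pd = dx.begin();
  const double *pp = dP.begin();
  for (int c = 0; c < nc; ++c) {
    const int cb = col_base[c];
    const int *rb = row_base.begin();
    const double *col = pp + (R_xlen_t)c * nr;
    for (int r = 0; r < nr; ++r) pd[rb[r] + cb] += col[r];
  }
  return dx;
}
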