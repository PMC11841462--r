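// Depthwise spatial convolution over the electrode axis: kernel (C x 1),
// depth multiplier D, valid padding (collapses the electrode axis).
// x: array (T, C*N, F) viewed as (T, C, N, F); w: array (C, D, F);
// out: array (T, N, F*D).
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".depthwise_fwd")]]
NumericVector depthwise_fwd(NumericVector x, int T, int C, int N, int F,
                            NumericVector w, int D) {
  NumericVector out(static_cast<R_xlen_t>(T) * N * F * D);
  const double *px = x.begin();
  const double *pw = w.begin();
  double *po = out.begin();
  for (int f = 0; f < F; ++f)
    for (int d = 0; d < D; ++d) {
      double *o = po + (static_cast<R_xlen_t>(f) * D + d) * T * N;
      for (int n = 0; n < N; ++n) {
        double *oc = o + static_cast<R_xlen_t>(n) * T;
        for (int h = 0; h < C; ++h) {
          const double wv = pw[h + d * C + f * C * D];
          const double *xc = px +
            (static_cast<R_xlen_t>(f) * C * N + n * C + h) * T;
          for (int t = 0; t < T; ++t) oc[t] += wv * xc[t];
        }
      }
    }
  out.attr("dim") = IntegerVector::create(T, N, F * D);
  return out;
}

// [[Rcpp::export(name = ".depthwise_bwd")]]
List depthwise_bwd(NumericVector x, int T, int C, int N, int F,
                   NumericVector w, int D, NumericVector dy) {
  NumericVector dx(x.size()), dw(w.size());
  const double *px = x.begin();
  const double *pw = w.begin();
  const double *pd = dy.begin();
  double *pdx = dx.begin();
  double *pdw = dw.begin();
  for (int f = 0; f < F; ++f)
    for (int d = 0; d < D; ++d)
      for (int n = 0; n < N; ++n) {
        const double *dyc = pd +
          (static_cast<R_xlen_t>(f) * D + d) * T * N +
          static_cast<R_xlen_t>(n) * T;
        for (int h = 0; h < C; ++h) {
          const R_xlen_t xoff =
            (static_cast<R_xlen_t>(f) * C * N + n * C + h) * T;
          const double *xc = px + xoff;
          double *dxc = pdx + xoff;
          const double wv = pw[h + d * C + f * C * D];
          double acc = 0;
          for (int t = 0; t < T; ++t) {
            acc += xc[t] * dyc[t];
            dxc[t] += wv * dyc[t];
          }
          pdw[h + d * C + f * C * D] += acc;
        }
      }
  dx.attr("dim") = IntegerVector::create(T, C * N, F);
  dw.attr("dim") = IntegerVector::create(C, D, F);
  return List::create(_["dx"] = dx, _["dWd"] = dw);
}
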