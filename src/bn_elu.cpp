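// Single-pass batch-normalization and ELU kernels. x is an (nb, C) view of
// an (L, B, C) activation array; per-channel statistics run over nb.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".bn_stats")]]
List bn_stats(NumericVector x, int nb, int nc) {
  NumericVector mu(nc), v(nc);
  for (int c = 0; c < nc; ++c) {
    const double *p = x.begin() + static_cast<R_xlen_t>(c) * nb;
    double s = 0, s2 = 0;
    for (int i = 0; i < nb; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    mu[c] = s / nb;
    double vv = s2 / nb - mu[c] * mu[c];
    v[c] = vv > 0 ? vv : 0;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// [[Rcpp::export(name = ".bn_apply")]]
List bn_apply(NumericVector x, int nb, int nc, NumericVector mu,
              NumericVector ivar, NumericVector gamma, NumericVector beta,
              bool need_xhat) {
  NumericVector out(x.size());
  NumericVector xhat(need_xhat ? x.size() : 0);
  for (int c = 0; c < nc; ++c) {
    const double *p = x.begin() + static_cast<R_xlen_t>(c) * nb;
    double *po = out.begin() + static_cast<R_xlen_t>(c) * nb;
    const double m = mu[c], iv = ivar[c], g = gamma[c], b = beta[c];
    if (need_xhat) {
      double *ph = xhat.begin() + static_cast<R_xlen_t>(c) * nb;
      for (int i = 0; i < nb; ++i) {
        ph[i] = (p[i] - m) * iv;
        po[i] = ph[i] * g + b;
      }
    } else {
      const double a = g * iv, bb = b - m * g * iv;
      for (int i = 0; i < nb; ++i) po[i] = p[i] * a + bb;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// Backward with batch statistics; returns dx, dgamma, dbeta.
// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector dy, NumericVector xhat, int nb, int nc,
            NumericVector gamma, NumericVector ivar, bool batch_stats) {
  NumericVector dx(dy.size()), dgamma(nc), dbeta(nc);
  for (int c = 0; c < nc; ++c) {
    const double *pd = dy.begin() + static_cast<R_xlen_t>(c) * nb;
    const double *ph = xhat.begin() + static_cast<R_xlen_t>(c) * nb;
    double *px = dx.begin() + static_cast<R_xlen_t>(c) * nb;
    double sd = 0, sdh = 0;
    for (int i = 0; i < nb; ++i) { sd += pd[i]; sdh += pd[i] * ph[i]; }
    dgamma[c] = sdh;
    dbeta[c] = sd;
    const double g = gamma[c], iv = ivar[c];
    if (batch_stats) {
      const double md = sd / nb, mdh = sdh / nb;
      for (int i = 0; i < nb; ++i)
        px[i] = (pd[i] - md - ph[i] * mdh) * g * iv;
    } else {
      for (int i = 0; i < nb; ++i) px[i] = pd[i] * g * iv;
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".elu_fwd")]]
NumericVector elu_fwd(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  return y;
}

// dy * elu'(x) expressed from the forward output y (elu' = 1 or y + 1).
// [[Rcpp::export(name = ".elu_bwd")]]
NumericVector elu_bwd(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[i] = y[i] > 0 ? dy[i] : dy[i] * (y[i] + 1);
  return dx;
}
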