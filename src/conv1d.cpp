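// 1-D convolution kernels shared by the temporal, pointwise and dilated
// causal layers. Activations use the (length, batch, channel) layout of the
// R side; im2col + BLAS GEMM keeps the hot path out of interpreted code.
// The batch axis is processed in chunks so the im2col buffer stays small.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// target im2col buffer size (doubles); ~32 MB
static const arma::uword kChunkBudget = 4u * 1024u * 1024u;

static int chunk_cols(int L_out, int CinK, int B) {
  arma::uword per_b = static_cast<arma::uword>(L_out) * CinK;
  int nb = per_b > 0 ? static_cast<int>(kChunkBudget / per_b) : B;
  if (nb < 1) nb = 1;
  if (nb > B) nb = B;
  return nb;
}

// Fill the im2col block for batch columns [b0, b0+nb).
static void im2col_block(const double *X, int L, int B, int Cin, int K,
                         int pad_left, int dilation, int L_out, int b0,
                         int nb, arma::mat &Xc) {
  Xc.zeros();
  for (int c = 0; c < Cin; ++c) {
    for (int k = 0; k < K; ++k) {
      double *col = Xc.colptr(c * K + k);
      const int off = k * dilation - pad_left;
      const int t0 = std::max(0, -off);
      const int t1 = std::min(L_out, L - off);
      for (int b = 0; b < nb; ++b) {
        const double *src = X + (static_cast<arma::uword>(c) * B + b0 + b) * L;
        double *dst = col + static_cast<arma::uword>(b) * L_out;
        for (int t = t0; t < t1; ++t) dst[t] = src[t + off];
      }
    }
  }
}

// X: numeric array (L, B, Cin); W: matrix (Cout, Cin*K) with column index
// (c-1)*K + k; returns array (L_out, B, Cout).
// [[Rcpp::export(name = ".conv1d_fwd")]]
NumericVector conv1d_fwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                         NumericVector bias, int K, int pad_left,
                         int pad_right, int dilation) {
  const int L = dims[0], B = dims[1], Cin = dims[2];
  const int span = (K - 1) * dilation;
  const int L_out = L + pad_left + pad_right - span;
  if (L_out < 1) stop("conv1d: output length < 1 (input too short for kernel)");
  const int Cout = w.nrow(), CinK = w.ncol();
  arma::mat Wm(w.begin(), Cout, CinK, false);
  NumericVector out(static_cast<R_xlen_t>(L_out) * B * Cout);
  const int nbc = chunk_cols(L_out, CinK, B);
  arma::mat Xc(static_cast<arma::uword>(L_out) * nbc, CinK);
  for (int b0 = 0; b0 < B; b0 += nbc) {
    const int nb = std::min(nbc, B - b0);
    arma::mat Xcv(Xc.memptr(), static_cast<arma::uword>(L_out) * nb, CinK,
                  false, true);
    im2col_block(x.begin(), L, B, Cin, K, pad_left, dilation, L_out, b0, nb,
                 Xcv);
    arma::mat Y = Xcv * Wm.t();  // (L_out*nb, Cout)
    for (int f = 0; f < Cout; ++f) {
      double *dst = out.begin() +
        (static_cast<arma::uword>(f) * B + b0) * L_out;
      const double *src = Y.colptr(f);
      const double bf = bias.size() == static_cast<R_xlen_t>(Cout) ? bias[f] : 0.0;
      for (arma::uword i = 0; i < static_cast<arma::uword>(L_out) * nb; ++i)
        dst[i] = src[i] + bf;
    }
  }
  out.attr("dim") = IntegerVector::create(L_out, B, Cout);
  return out;
}

// Backward pass: returns list(dx, dw, db).
// [[Rcpp::export(name = ".conv1d_bwd")]]
List conv1d_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                NumericVector dy, int K, int pad_left, int pad_right,
                int dilation, bool need_dx) {
  const int L = dims[0], B = dims[1], Cin = dims[2];
  const int span = (K - 1) * dilation;
  const int L_out = L + pad_left + pad_right - span;
  const int Cout = w.nrow(), CinK = w.ncol();
  arma::mat Wm(w.begin(), Cout, CinK, false);
  arma::mat dW(Cout, CinK, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);

  NumericVector dxv;
  double *dxp = nullptr;
  if (need_dx) {
    dxv = NumericVector(static_cast<R_xlen_t>(L) * B * Cin);
    dxv.attr("dim") = IntegerVector::create(L, B, Cin);
    dxp = dxv.begin();
  }
  const int nbc = chunk_cols(L_out, CinK, B);
  arma::mat Xc(static_cast<arma::uword>(L_out) * nbc, CinK);
  arma::mat dYc(static_cast<arma::uword>(L_out) * nbc, Cout);
  for (int b0 = 0; b0 < B; b0 += nbc) {
    const int nb = std::min(nbc, B - b0);
    const arma::uword rows = static_cast<arma::uword>(L_out) * nb;
    arma::mat Xcv(Xc.memptr(), rows, CinK, false, true);
    im2col_block(x.begin(), L, B, Cin, K, pad_left, dilation, L_out, b0, nb,
                 Xcv);
    arma::mat dYv(dYc.memptr(), rows, Cout, false, true);
    for (int f = 0; f < Cout; ++f) {
      const double *src = dy.begin() +
        (static_cast<arma::uword>(f) * B + b0) * L_out;
      std::copy(src, src + rows, dYv.colptr(f));
    }
    dW += dYv.t() * Xcv;
    db += arma::sum(dYv, 0);
    if (need_dx) {
      arma::mat dXc = dYv * Wm;                // (L_out*nb, Cin*K)
      for (int c = 0; c < Cin; ++c) {
        for (int k = 0; k < K; ++k) {
          const double *col = dXc.colptr(c * K + k);
          const int off = k * dilation - pad_left;
          const int t0 = std::max(0, -off);
          const int t1 = std::min(L_out, L - off);
          for (int b = 0; b < nb; ++b) {
            double *dst = dxp +
              (static_cast<arma::uword>(c) * B + b0 + b) * L;
            const double *src = col + static_cast<arma::uword>(b) * L_out;
            for (int t = t0; t < t1; ++t) dst[t + off] += src[t];
          }
        }
      }
    }
  }
  NumericMatrix dwm(Cout, CinK);
  std::copy(dW.begin(), dW.end(), dwm.begin());
  return List::create(_["dx"] = dxv, _["dw"] = dwm,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
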