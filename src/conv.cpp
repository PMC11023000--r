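// Fused 'same' 3x3 convolution on the channel-first (C, S, B) layout used by
// the DPN/PPN trunk. The spatial geometry (which source voxel feeds each
// kernel tap at each output position, 0 for zero padding) is precomputed in
// R and passed as a 9 x S index matrix.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Builds the im2col matrix (9*C, S*B) and returns the pre-activation
// y = W * xc + b as (C_out, S*B), optionally with xc for the backward pass.
// src: 9 x S, 1-based source spatial index or 0 for padding.
// [[Rcpp::export(name = ".conv_fwd_cpp")]]
List conv_fwd_cpp(NumericVector x, IntegerVector xdim, NumericMatrix W,
                  NumericVector b, IntegerMatrix src, bool return_xc) {
  const int C = xdim[0], S = xdim[1], B = xdim[2];
  const int K = 9 * C;
  NumericMatrix xcR(K, S * B);
  const double *xp = x.begin();
  double *xc = xcR.begin();
  const int *sp = src.begin();
  for (int bb = 0; bb < B; ++bb) {
    const double *xb = xp + (size_t)bb * C * S;
    double *col = xc + (size_t)bb * S * K;
    for (int s = 0; s < S; ++s) {
      double *cs = col + (size_t)s * K;
      const int *ss = sp + 9 * s;
      for (int o = 0; o < 9; ++o) {
        int s2 = ss[o];
        if (s2 == 0) {
          for (int c = 0; c < C; ++c) cs[o + 9 * c] = 0.0;
        } else {
          const double *xv = xb + (size_t)(s2 - 1) * C;
          for (int c = 0; c < C; ++c) cs[o + 9 * c] = xv[c];
        }
      }
    }
  }
  arma::mat xcA(xc, K, (size_t)S * B, false, true);
  arma::mat WA(W.begin(), W.nrow(), W.ncol(), false, true);
  NumericMatrix yR(W.nrow(), S * B);
  arma::mat yA(yR.begin(), W.nrow(), (size_t)S * B, false, true);
  yA = WA * xcA;
  arma::vec bA(b.begin(), b.size(), false, true);
  yA.each_col() += bA;
  if (return_xc) return List::create(Named("y") = yR, Named("xc") = xcR);
  return List::create(Named("y") = yR);
}

// LeakyReLU + inverted dropout in one pass. Returns the activation and (in
// training mode) the dropout mask needed for the backward pass. Dropout
// draws use R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export(name = ".act_dropout_cpp")]]
List act_dropout_cpp(NumericVector y, double slope, double dropout,
                     bool train) {
  R_xlen_t n = y.size();
  NumericVector a(n);
  const double *yp = y.begin();
  double *ap = a.begin();
  if (train && dropout > 0) {
    NumericVector mask(n);
    double *mp = mask.begin();
    const double keep = 1.0 - dropout;
    for (R_xlen_t i = 0; i < n; ++i) {
      double m = (unif_rand() >= dropout) ? 1.0 / keep : 0.0;
      mp[i] = m;
      double v = yp[i];
      ap[i] = (v > 0 ? v : slope * v) * m;
    }
    return List::create(Named("a") = a, Named("mask") = mask);
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = yp[i];
    ap[i] = v > 0 ? v : slope * v;
  }
  return List::create(Named("a") = a);
}

// Backward of the fused step: dy = dx * mask * dLeakyReLU(pre).
// [[Rcpp::export(name = ".act_dropout_bwd_cpp")]]
NumericVector act_dropout_bwd_cpp(NumericVector dx, NumericVector pre,
                                  Nullable<NumericVector> mask, double slope) {
  R_xlen_t n = dx.size();
  NumericVector dy(n);
  const double *dp = dx.begin(), *pp = pre.begin();
  double *op = dy.begin();
  if (mask.isNotNull()) {
    NumericVector m(mask);
    const double *mp = m.begin();
    for (R_xlen_t i = 0; i < n; ++i)
      op[i] = dp[i] * mp[i] * (pp[i] > 0 ? 1.0 : slope);
  } else {
    for (R_xlen_t i = 0; i < n; ++i)
      op[i] = dp[i] * (pp[i] > 0 ? 1.0 : slope);
  }
  return dy;
}
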