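// Fused forward/backward passes through the 4-layer conv trunk shared by
// DPN and PPN. Keeping the whole trunk in compiled code keeps the per-batch
// cost of mini-batch training low enough for the 100-epoch protocols.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>

using namespace Rcpp;

// xorshift64* stream seeded from R's RNG: dropout masks stay reproducible
// under set.seed() while avoiding one unif_rand() call per activation.
namespace {
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  double next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return (double)((s * 0x2545F4914F6CDD1DULL) >> 11) / 9007199254740992.0;
  }
};

void im2col(const double *x, int C, int S, int B, const int *src, double *xc) {
  for (int bb = 0; bb < B; ++bb) {
    const double *xb = x + (size_t)bb * C * S;
    double *col = xc + (size_t)bb * S * 9 * C;
    for (int s = 0; s < S; ++s) {
      double *cs = col + (size_t)s * 9 * C;
      const int *ss = src + 9 * s;
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
}
} // namespace

// Forward through the conv trunk. x0: (2, S, B). Ws: list of (C_out, 9*C_in)
// weight matrices; bs: list of bias vectors. Returns the final activation
// plus the per-layer im2col matrices, pre-activations and dropout masks
// needed by trunk_bwd.
// [[Rcpp::export(name = ".trunk_fwd_cpp")]]
List trunk_fwd(NumericVector x0, IntegerVector xdim, List Ws, List bs,
               IntegerMatrix src, double slope, double dropout, bool train,
               bool channel_dropout) {
  const int S = xdim[1], B = xdim[2];
  const int L = Ws.size();
  List xcs(L), pres(L), masks(L);
  XorShift rng((uint64_t)(unif_rand() * 9007199254740992.0));
  const double keep = 1.0 - dropout;
  NumericVector x = x0;
  int C = xdim[0];
  for (int l = 0; l < L; ++l) {
    NumericMatrix W = Ws[l];
    NumericVector b = bs[l];
    const int C_out = W.nrow();
    NumericMatrix xcR(9 * C, S * B);
    im2col(x.begin(), C, S, B, src.begin(), xcR.begin());
    arma::mat xcA(xcR.begin(), 9 * C, (size_t)S * B, false, true);
    arma::mat WA(W.begin(), C_out, 9 * C, false, true);
    NumericMatrix preR(C_out, S * B);
    arma::mat preA(preR.begin(), C_out, (size_t)S * B, false, true);
    preA = WA * xcA;
    arma::vec bA(b.begin(), b.size(), false, true);
    preA.each_col() += bA;
    NumericVector a((R_xlen_t)C_out * S * B);
    const double *pp = preR.begin();
    double *ap = a.begin();
    const R_xlen_t n = a.size();
    if (train && dropout > 0 && channel_dropout) {
      // 2D (channel-wise) dropout: one Bernoulli per feature map per sample
      NumericVector mask(n);
      double *mp = mask.begin();
      for (int bb = 0; bb < B; ++bb) {
        std::vector<double> cm(C_out);
        for (int c = 0; c < C_out; ++c)
          cm[c] = (rng.next() >= dropout) ? 1.0 / keep : 0.0;
        double *mb = mp + (size_t)bb * C_out * S;
        const double *pb = pp + (size_t)bb * C_out * S;
        double *ab = ap + (size_t)bb * C_out * S;
        for (int s = 0; s < S; ++s)
          for (int c = 0; c < C_out; ++c) {
            size_t i = c + (size_t)s * C_out;
            mb[i] = cm[c];
            double v = pb[i];
            ab[i] = (v > 0 ? v : slope * v) * cm[c];
          }
      }
      masks[l] = mask;
    } else if (train && dropout > 0) {
      NumericVector mask(n);
      double *mp = mask.begin();
      for (R_xlen_t i = 0; i < n; ++i) {
        double m = (rng.next() >= dropout) ? 1.0 / keep : 0.0;
        mp[i] = m;
        double v = pp[i];
        ap[i] = (v > 0 ? v : slope * v) * m;
      }
      masks[l] = mask;
    } else {
      for (R_xlen_t i = 0; i < n; ++i) {
        double v = pp[i];
        ap[i] = v > 0 ? v : slope * v;
      }
      masks[l] = R_NilValue;
    }
    xcs[l] = xcR;
    pres[l] = preR;
    x = a;
    C = C_out;
  }
  return List::create(Named("out") = x, Named("xc") = xcs,
                      Named("pre") = pres, Named("mask") = masks);
}

// Backward through the conv trunk. dx: gradient at the trunk output
// (C_last, S*B). Returns per-layer dW/db and, optionally, the gradient of
// the tiled channel-2 input vector (4 x B), obtained by summing the
// channel-2 input gradient over the n tiled columns.
// [[Rcpp::export(name = ".trunk_bwd_cpp")]]
List trunk_bwd(NumericVector dx0, List Ws, List xcs, List pres, List masks,
               IntegerMatrix src, IntegerVector xdim, double slope,
               bool need_dinput) {
  const int S = xdim[1], B = xdim[2];
  const int L = Ws.size();
  List dWs(L), dbs(L);
  NumericVector dx = dx0;
  for (int l = L - 1; l >= 0; --l) {
    NumericMatrix W = Ws[l];
    NumericMatrix xc = xcs[l];
    NumericMatrix pre = pres[l];
    const int C_out = W.nrow();
    const int KC = W.ncol();           // 9 * C_in
    const int C_in = KC / 9;
    const R_xlen_t n = (R_xlen_t)C_out * S * B;
    // dy = dx * mask * dLeaky(pre)
    NumericVector dy(n);
    const double *dxp = dx.begin(), *pp = pre.begin();
    double *dyp = dy.begin();
    if (masks[l] != R_NilValue) {
      NumericVector mask = masks[l];
      const double *mp = mask.begin();
      for (R_xlen_t i = 0; i < n; ++i)
        dyp[i] = dxp[i] * mp[i] * (pp[i] > 0 ? 1.0 : slope);
    } else {
      for (R_xlen_t i = 0; i < n; ++i)
        dyp[i] = dxp[i] * (pp[i] > 0 ? 1.0 : slope);
    }
    arma::mat dyA(dyp, C_out, (size_t)S * B, false, true);
    arma::mat xcA(xc.begin(), KC, (size_t)S * B, false, true);
    NumericMatrix dW(C_out, KC);
    arma::mat dWA(dW.begin(), C_out, KC, false, true);
    dWA = dyA * xcA.t();
    NumericVector db(C_out);
    arma::vec dbA(db.begin(), C_out, false, true);
    dbA = arma::sum(dyA, 1);
    dWs[l] = dW;
    dbs[l] = db;
    if (l > 0 || need_dinput) {
      // dx_prev = conv(dy, flipped transposed W)
      NumericMatrix Wt(C_in, 9 * C_out);
      const double *wp = W.begin();
      double *wtp = Wt.begin();
      // W(co, o + 9*c) -> Wt(c, (8-o) + 9*co)
      for (int c = 0; c < C_in; ++c)
        for (int o = 0; o < 9; ++o)
          for (int co = 0; co < C_out; ++co)
            wtp[c + (size_t)C_in * ((8 - o) + 9 * co)] =
              wp[co + (size_t)C_out * (o + 9 * c)];
      NumericMatrix dyc(9 * C_out, S * B);
      im2col(dyp, C_out, S, B, src.begin(), dyc.begin());
      arma::mat dycA(dyc.begin(), 9 * C_out, (size_t)S * B, false, true);
      arma::mat WtA(Wt.begin(), C_in, 9 * C_out, false, true);
      NumericVector dxn((R_xlen_t)C_in * S * B);
      arma::mat dxA(dxn.begin(), C_in, (size_t)S * B, false, true);
      dxA = WtA * dycA;
      dx = dxn;
    }
  }
  if (need_dinput) {
    // dvec[r, b] = sum over histogram columns of channel-2 input gradient
    NumericMatrix dvec(4, B);
    const int ncol = S / 4;
    const double *dxp = dx.begin();
    for (int bb = 0; bb < B; ++bb)
      for (int col = 0; col < ncol; ++col)
        for (int r = 0; r < 4; ++r)
          dvec(r, bb) += dxp[1 + 2 * (size_t)(r + 4 * col) + 2 * (size_t)S * bb];
    return List::create(Named("dW") = dWs, Named("db") = dbs,
                        Named("dvec") = dvec);
  }
  return List::create(Named("dW") = dWs, Named("db") = dbs);
}
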