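// Compiled kernels for the hot paths: im2col expansion of 3x3 convolutions
// and the per-group scaled-dot-attention forward/backward loops.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 window with zero padding over B stacked H x W maps in
// position-major layout (p = h + w*H within a sample, samples stacked
// row-wise).  Output columns are ordered offset-fastest within each input
// channel; offsets enumerate dw in -1..1 (outer), dh in -1..1 (inner).
// [[Rcpp::export(name = ".im2col3_cpp")]]
NumericMatrix im2col3_cpp(const NumericMatrix& x, int H, int W, int B) {
  const int N = H * W;
  const int C = x.ncol();
  NumericMatrix out(B * N, 9 * C);
  const double* px = x.begin();
  double* po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)B * N;
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (R_xlen_t)c * nrow;
    int o = 0;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh, ++o) {
        double* oc = po + ((R_xlen_t)(o + 9 * c)) * nrow;
        for (int b = 0; b < B; ++b) {
          const double* xb = xc + (R_xlen_t)b * N;
          double* ob = oc + (R_xlen_t)b * N;
          for (int w2 = 0; w2 < W; ++w2) {
            const int ws = w2 + dw;
            double* od = ob + w2 * H;
            if (ws < 0 || ws >= W) continue;  // zero padding (already 0)
            const double* xs = xb + ws * H;
            const int h0 = (dh < 0) ? -dh : 0;
            const int h1 = (dh > 0) ? H - dh : H;
            for (int h = h0; h < h1; ++h) od[h] = xs[h + dh];
          }
        }
      }
    }
  }
  return out;
}

static arma::mat softmax_cols_arma(arma::mat S) {
  arma::rowvec mx = arma::max(S, 0);
  S.each_row() -= mx;
  S = arma::exp(S);
  arma::rowvec cs = arma::sum(S, 0);
  S.each_row() /= cs;
  return S;
}

// Grouped scaled-dot attention forward.  F, G, Hm are (B*N) x Cbar
// projected maps; groups is a list of 1-based position-index vectors.
// Returns the aggregated map z and the per-group affinity matrices.
// [[Rcpp::export(name = ".att_fwd_cpp")]]
List att_fwd_cpp(const arma::mat& F, const arma::mat& G, const arma::mat& Hm,
                 const List& groups, double isd) {
  const int ng = groups.size();
  arma::mat z(F.n_rows, F.n_cols, arma::fill::zeros);
  List As(ng);
  for (int gi = 0; gi < ng; ++gi) {
    IntegerVector gv = groups[gi];
    arma::uvec idx(gv.size());
    for (int i = 0; i < gv.size(); ++i) idx[i] = gv[i] - 1;
    arma::mat Fp = F.rows(idx);
    arma::mat Gp = G.rows(idx);
    arma::mat S = Fp * Gp.t() * isd;
    arma::mat A = softmax_cols_arma(S);
    z.rows(idx) = A.t() * Hm.rows(idx);
    As[gi] = A;
  }
  return List::create(_["z"] = z, _["A"] = As);
}

// Grouped attention backward: given dz (cotangent of z), reproduce the
// pullback through aggregation and the column softmax.
// [[Rcpp::export(name = ".att_bwd_cpp")]]
List att_bwd_cpp(const arma::mat& dz, const List& As, const arma::mat& F,
                 const arma::mat& G, const arma::mat& Hm, const List& groups,
                 double isd) {
  arma::mat dF(F.n_rows, F.n_cols, arma::fill::zeros);
  arma::mat dG(F.n_rows, F.n_cols, arma::fill::zeros);
  arma::mat dH(F.n_rows, F.n_cols, arma::fill::zeros);
  const int ng = groups.size();
  for (int gi = 0; gi < ng; ++gi) {
    IntegerVector gv = groups[gi];
    arma::uvec idx(gv.size());
    for (int i = 0; i < gv.size(); ++i) idx[i] = gv[i] - 1;
    arma::mat A = As[gi];
    arma::mat dZp = dz.rows(idx);
    arma::mat Hp = Hm.rows(idx);
    arma::mat dA = Hp * dZp.t();
    dH.rows(idx) = A * dZp;
    arma::rowvec s = arma::sum(A % dA, 0);
    arma::mat dS = A % (dA.each_row() - s);
    dF.rows(idx) = (dS * G.rows(idx)) * isd;
    dG.rows(idx) = (dS.t() * F.rows(idx)) * isd;
  }
  return List::create(_["dF"] = dF, _["dG"] = dG, _["dH"] = dH);
}
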