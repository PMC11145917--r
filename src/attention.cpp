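// Batched windowed multi-head self-attention kernels.
//
// Q, K, V are cubes of shape (ws, dh, S): ws tokens per window, dh head
// dimension, S = nwin * B * H slices ordered window-fastest, then batch,
// then head. `bias` is the relative-position bias (ws, ws, H) shared across
// windows; `mask` is the shifted-window attention mask (ws, ws, nwin),
// additive with large negative entries for forbidden (wrapped) pairs.
// Empty cubes disable the corresponding term.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::cube& Q, const arma::cube& K,
                            const arma::cube& V, double scale,
                            const arma::cube& bias, const arma::cube& mask,
                            int nwin, int B) {
  const uword ws = Q.n_rows, dh = Q.n_cols, S = Q.n_slices;
  const uword nwinB = (uword)(nwin * B);
  const bool has_bias = bias.n_elem > 0, has_mask = mask.n_elem > 0;
  cube out(ws, dh, S), P(ws, ws, S);
  mat scores(ws, ws);
  for (uword s = 0; s < S; ++s) {
    const uword wb = s % nwinB;
    const uword w = wb % (uword)nwin;
    const uword h = s / nwinB;
    scores = Q.slice(s) * K.slice(s).t() * scale;
    if (has_bias) scores += bias.slice(h);
    if (has_mask) scores += mask.slice(w);
    // row-wise softmax
    for (uword i = 0; i < ws; ++i) {
      rowvec r = scores.row(i);
      r -= r.max();
      r = exp(r);
      scores.row(i) = r / accu(r);
    }
    P.slice(s) = scores;
    out.slice(s) = scores * V.slice(s);
  }
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("P") = P);
}

// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::cube& dOut, const arma::cube& Q,
                             const arma::cube& K, const arma::cube& V,
                             const arma::cube& P, double scale,
                             int nwin, int B, int H) {
  const uword ws = Q.n_rows, dh = Q.n_cols, S = Q.n_slices;
  const uword nwinB = (uword)(nwin * B);
  cube dQ(ws, dh, S), dK(ws, dh, S), dV(ws, dh, S);
  cube dbias(ws, ws, (uword)H, fill::zeros);
  mat dP(ws, ws), dS(ws, ws);
  for (uword s = 0; s < S; ++s) {
    const uword h = s / nwinB;
    dV.slice(s) = P.slice(s).t() * dOut.slice(s);
    dP = dOut.slice(s) * V.slice(s).t();
    // softmax backward: dS = P % (dP - rowsum(dP % P))
    vec rs = sum(dP % P.slice(s), 1);
    dS = P.slice(s) % (dP.each_col() - rs);
    dbias.slice(h) += dS;
    dQ.slice(s) = dS * K.slice(s) * scale;
    dK.slice(s) = dS.t() * Q.slice(s) * scale;
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV,
                            Rcpp::Named("dbias") = dbias);
}
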