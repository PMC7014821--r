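// Residual-bootstrap inner loop: refit SH coefficients for permuted-residual
// instances and pool singular values of the per-order matrices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// yhat, resid: DWI-only vectors (length nu), ordered shell by shell as
// shellPos indexes them.  perms: nu x N matrix of 1-based permutation
// indices.  pinv: per-shell (ncoef x n_b) pseudoinverse matrices.
// blockSizes: 2l+1 per even order l.  Returns N x nComp pooled sigma'.
// [[Rcpp::export]]
arma::mat cppNullSigmas(const arma::vec& yhat, const arma::vec& resid,
                        const arma::imat& perms, double scale,
                        const Rcpp::List& pinv, const Rcpp::List& shellPos,
                        const arma::ivec& blockSizes) {
  const uword nu = yhat.n_elem;
  const uword N = perms.n_cols;
  const int k = pinv.size();
  std::vector<mat> P(k);
  std::vector<uvec> idx(k);
  for (int b = 0; b < k; ++b) {
    P[b] = Rcpp::as<mat>(pinv[b]);
    idx[b] = Rcpp::as<uvec>(shellPos[b]) - 1;
  }
  const uword ncoef = P[0].n_rows;
  const uword nl = blockSizes.n_elem;
  uword nComp = 0;
  for (uword l = 0; l < nl; ++l) {
    uword c = std::min<uword>(k, blockSizes[l]);
    if (c > nComp) nComp = c;
  }
  mat out(N, nComp, fill::zeros);
  vec yp(nu);
  mat C(k, ncoef);
  for (uword j = 0; j < N; ++j) {
    for (uword t = 0; t < nu; ++t)
      yp[t] = yhat[t] + scale * resid[perms(t, j) - 1];
    for (int b = 0; b < k; ++b)
      C.row(b) = (P[b] * yp.elem(idx[b])).t();
    rowvec s2(nComp, fill::zeros);
    uword off = 0;
    for (uword l = 0; l < nl; ++l) {
      mat Sl = C.cols(off, off + blockSizes[l] - 1);
      vec sv = svd(Sl);
      for (uword i = 0; i < sv.n_elem && i < nComp; ++i)
        s2[i] += sv[i] * sv[i];
      off += blockSizes[l];
    }
    out.row(j) = sqrt(s2);
  }
  return out;
}
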