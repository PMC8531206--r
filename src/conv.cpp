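// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Direct 3D convolution over precomputed im2col index maps. Samples are
// processed in small chunks so the patch buffer stays cache-resident; large
// chunks thrash the cache and cost far more than the GEMM itself.

static const arma::uword CHUNK = 8;

//' @title conv3d forward over an index plan (internal)
//' @param Xp padded input, n_pad x N (batch in columns)
//' @param idx 1-based im2col indices, ksize x n_out
//' @param W kernel matrix, ksize x F
//' @param b bias, length F
//' @return F x (n_out*N) pre-activation matrix
//' @keywords internal
// [[Rcpp::export(name = ".conv_fwd_cpp")]]
arma::mat conv_fwd_cpp(const arma::mat& Xp, const IntegerMatrix& idx,
                       const arma::mat& W, const arma::vec& b) {
  const arma::uword ks = idx.nrow(), n_out = idx.ncol(), N = Xp.n_cols,
                    F = W.n_cols, P = ks * n_out;
  arma::mat Out(F, n_out * N);
  const int* ip = idx.begin();
  arma::mat M(ks, n_out * std::min(CHUNK, N));
  for (arma::uword c0 = 0; c0 < N; c0 += CHUNK) {
    const arma::uword nc = std::min(CHUNK, N - c0);
    for (arma::uword n = 0; n < nc; ++n) {
      const double* xcol = Xp.colptr(c0 + n);
      double* m = M.colptr(n * n_out);
      for (arma::uword j = 0; j < P; ++j) m[j] = xcol[ip[j] - 1];
    }
    Out.cols(c0 * n_out, (c0 + nc) * n_out - 1) =
      W.t() * M.cols(0, nc * n_out - 1);
  }
  Out.each_col() += b;
  return Out;
}

//' @title conv3d backward over an index plan (internal)
//' @param Xp padded input, n_pad x N
//' @param idx 1-based im2col indices, ksize x n_out
//' @param W kernel matrix, ksize x F
//' @param dZ upstream gradient, F x (n_out*N)
//' @return list with dW, db, dXp
//' @keywords internal
// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(const arma::mat& Xp, const IntegerMatrix& idx,
                  const arma::mat& W, const arma::mat& dZ) {
  const arma::uword ks = idx.nrow(), n_out = idx.ncol(), N = Xp.n_cols,
                    F = W.n_cols, P = ks * n_out;
  arma::mat dW(ks, F, arma::fill::zeros);
  arma::vec db = arma::sum(dZ, 1);
  arma::mat dXp(Xp.n_rows, N, arma::fill::zeros);
  const int* ip = idx.begin();
  const arma::uword nc0 = std::min(CHUNK, N);
  arma::mat M(ks, n_out * nc0), dM(ks, n_out * nc0);
  for (arma::uword c0 = 0; c0 < N; c0 += CHUNK) {
    const arma::uword nc = std::min(CHUNK, N - c0);
    for (arma::uword n = 0; n < nc; ++n) {
      const double* xcol = Xp.colptr(c0 + n);
      double* m = M.colptr(n * n_out);
      for (arma::uword j = 0; j < P; ++j) m[j] = xcol[ip[j] - 1];
    }
    dW += M.cols(0, nc * n_out - 1) *
      dZ.cols(c0 * n_out, (c0 + nc) * n_out - 1).t();
    dM.cols(0, nc * n_out - 1) =
      W * dZ.cols(c0 * n_out, (c0 + nc) * n_out - 1);
    for (arma::uword n = 0; n < nc; ++n) {
      double* dx = dXp.colptr(c0 + n);
      const double* dm = dM.colptr(n * n_out);
      for (arma::uword j = 0; j < P; ++j) dx[ip[j] - 1] += dm[j];
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dXp"] = dXp);
}
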