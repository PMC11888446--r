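// Fused multi-head scaled-dot-product attention kernels.
// Q, K, V and dO are (B*T) x H matrices whose rows are ordered by example
// then position (position fastest); heads occupy contiguous column blocks.
// mask is the B x T attention mask; masked key columns are excluded by
// setting their scores to -inf before the row softmax.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
Rcpp::List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                            const arma::mat& V, const arma::imat& mask,
                            int B, int T, int nh, bool want_cache) {
  const int H = Q.n_cols;
  const int dh = H / nh;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat O(B * T, H, fill::zeros);
  cube A;
  if (want_cache) A.set_size(T, T, (size_t)B * nh);
  for (int b = 0; b < B; ++b) {
    const span rows(b * T, b * T + T - 1);
    for (int h = 0; h < nh; ++h) {
      const span cols(h * dh, (h + 1) * dh - 1);
      mat S = Q(rows, cols) * K(rows, cols).t() * scale;
      for (int j = 0; j < T; ++j) {
        if (mask(b, j) == 0) S.col(j).fill(-datum::inf);
      }
      vec mx = max(S, 1);
      S.each_col() -= mx;
      S = exp(S);
      vec rs = sum(S, 1);
      S.each_col() /= rs;
      O(rows, cols) = S * V(rows, cols);
      if (want_cache) A.slice((size_t)b * nh + h) = S;
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// [[Rcpp::export]]
Rcpp::List attn_backward_cpp(const arma::mat& dO, const arma::cube& A,
                             const arma::mat& Q, const arma::mat& K,
                             const arma::mat& V, int B, int T, int nh) {
  const int H = Q.n_cols;
  const int dh = H / nh;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dQ(B * T, H, fill::zeros), dK(B * T, H, fill::zeros),
      dV(B * T, H, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const span rows(b * T, b * T + T - 1);
    for (int h = 0; h < nh; ++h) {
      const span cols(h * dh, (h + 1) * dh - 1);
      const mat& Ab = A.slice((size_t)b * nh + h);
      mat dOb = dO(rows, cols);
      mat dA = dOb * V(rows, cols).t();
      dV(rows, cols) = Ab.t() * dOb;
      vec rowdot = sum(dA % Ab, 1);
      mat dS = Ab % (dA.each_col() - rowdot);
      dQ(rows, cols) = dS * K(rows, cols) * scale;
      dK(rows, cols) = dS.t() * Q(rows, cols) * scale;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}
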