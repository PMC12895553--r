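// Recurrent core of the main network: batched forward rollout and
// backpropagation through time. The input/output projections are plain
// matrix products; only the recurrent update needs the time loop, so the
// hot loops live here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: [n_in, S*T] with time-major column blocks; returns H [nh, S*T] and
// Y [n_out, S*T].
// [[Rcpp::export(name = ".rnn_fwd_cpp")]]
Rcpp::List rnn_fwd_cpp(const arma::mat& W_ih, const arma::vec& b_ih,
                       const arma::mat& W_hh, const arma::vec& b_hh,
                       const arma::mat& W_ho, const arma::vec& b_ho,
                       const arma::mat& X, const int S, const int T,
                       const arma::mat& h0) {
  const uword nh = W_hh.n_rows;
  mat P = W_ih * X;
  P.each_col() += b_ih + b_hh;
  mat H(nh, S * (uword)T);
  mat h = h0;
  for (int t = 0; t < T; ++t) {
    h = tanh(P.cols(t * S, (t + 1) * S - 1) + W_hh * h);
    H.cols(t * S, (t + 1) * S - 1) = h;
  }
  mat Y = W_ho * H;
  Y.each_col() += b_ho;
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("Y") = Y);
}

// gY: [n_out, S*T] gradient at the linear outputs. Returns per-block
// parameter gradients (b_ih and b_hh share the same gradient).
// [[Rcpp::export(name = ".rnn_bwd_cpp")]]
Rcpp::List rnn_bwd_cpp(const arma::mat& W_hh, const arma::mat& W_ho,
                       const arma::mat& X, const arma::mat& H, const arma::mat& gY,
                       const int S, const int T, const arma::mat& h0) {
  const uword nh = W_hh.n_rows;
  mat GHo = W_ho.t() * gY;
  mat Gpre(nh, S * (uword)T);
  mat gW_hh(nh, nh, fill::zeros);
  mat gh_next(nh, S, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat h_t = H.cols(t * S, (t + 1) * S - 1);
    mat gpre = (GHo.cols(t * S, (t + 1) * S - 1) + gh_next) % (1 - h_t % h_t);
    Gpre.cols(t * S, (t + 1) * S - 1) = gpre;
    if (t > 0) {
      gW_hh += gpre * H.cols((t - 1) * S, t * S - 1).t();
    } else {
      gW_hh += gpre * h0.t();
    }
    gh_next = W_hh.t() * gpre;
  }
  vec gb_h = sum(Gpre, 1);
  return Rcpp::List::create(
      Rcpp::Named("W_ih") = Gpre * X.t(),
      Rcpp::Named("b_h") = gb_h,
      Rcpp::Named("W_hh") = gW_hh,
      Rcpp::Named("W_ho") = gY * H.t(),
      Rcpp::Named("b_ho") = vec(sum(gY, 1)));
}
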