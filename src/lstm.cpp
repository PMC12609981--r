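// Batched single-direction LSTM forward / backward-through-time kernels.
//
// Layout convention shared with the R code: sequences are stored time-major
// in big matrices of B*T rows, where row b + t*B (0-based) holds window b at
// time step t. Gate order within the 4h columns is [input, forget, cell,
// output]. The input projection X*Wx + bias is precomputed in R as one large
// matrix product; only the recurrent part runs here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& Gx, const arma::mat& Wh,
                            const int B, const int T) {
  const int h = Wh.n_rows;
  if ((int)Gx.n_rows != B * T || (int)Gx.n_cols != 4 * h)
    Rcpp::stop("lstm_forward_cpp: Gx must be (B*T) x 4h");

  mat H(B * T, h), C(B * T, h);
  mat Ig(B * T, h), Fg(B * T, h), Gg(B * T, h), Og(B * T, h);
  mat hprev(B, h, fill::zeros), cprev(B, h, fill::zeros);

  for (int t = 0; t < T; ++t) {
    const span rows(t * B, t * B + B - 1);
    mat g = Gx.rows(rows) + hprev * Wh;
    mat ig = sigmoid(g.cols(0, h - 1));
    mat fg = sigmoid(g.cols(h, 2 * h - 1));
    mat gg = tanh(g.cols(2 * h, 3 * h - 1));
    mat og = sigmoid(g.cols(3 * h, 4 * h - 1));
    mat c = fg % cprev + ig % gg;
    mat hh = og % tanh(c);
    Ig.rows(rows) = ig; Fg.rows(rows) = fg;
    Gg.rows(rows) = gg; Og.rows(rows) = og;
    C.rows(rows) = c;   H.rows(rows) = hh;
    hprev = hh; cprev = c;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("I") = Ig,
                            Rcpp::Named("F") = Fg, Rcpp::Named("G") = Gg,
                            Rcpp::Named("O") = Og, Rcpp::Named("C") = C);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dH, const arma::mat& Wh,
                             const arma::mat& Ig, const arma::mat& Fg,
                             const arma::mat& Gg, const arma::mat& Og,
                             const arma::mat& C, const arma::mat& H,
                             const int B, const int T) {
  const int h = Wh.n_rows;
  mat dGx(B * T, 4 * h);
  mat dWh(h, 4 * h, fill::zeros);
  mat dh_next(B, h, fill::zeros), dc_next(B, h, fill::zeros);

  for (int t = T - 1; t >= 0; --t) {
    const span rows(t * B, t * B + B - 1);
    mat dh = dH.rows(rows) + dh_next;
    mat tc = tanh(C.rows(rows));
    mat ig = Ig.rows(rows), fg = Fg.rows(rows);
    mat gg = Gg.rows(rows), og = Og.rows(rows);
    mat dc = dh % og % (1.0 - tc % tc) + dc_next;
    mat cprev = (t > 0) ? mat(C.rows(span((t - 1) * B, t * B - 1)))
                        : mat(B, h, fill::zeros);
    mat dgates(B, 4 * h);
    dgates.cols(0, h - 1)         = dc % gg % ig % (1.0 - ig);
    dgates.cols(h, 2 * h - 1)     = dc % cprev % fg % (1.0 - fg);
    dgates.cols(2 * h, 3 * h - 1) = dc % ig % (1.0 - gg % gg);
    dgates.cols(3 * h, 4 * h - 1) = dh % tc % og % (1.0 - og);
    dGx.rows(rows) = dgates;
    if (t > 0) dWh += mat(H.rows(span((t - 1) * B, t * B - 1))).t() * dgates;
    dh_next = dgates * Wh.t();
    dc_next = dc % fg;
  }
  return Rcpp::List::create(Rcpp::Named("dGx") = dGx,
                            Rcpp::Named("dWh") = dWh);
}
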