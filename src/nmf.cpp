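// Kullback-Leibler NMF by multiplicative updates.
// X (m x n) ~ W (m x r) %*% H (r x n), all entrywise nonnegative.
// Zero rows/columns are handled by eps-flooring inside the update
// denominators and inside the ratio X / (WH).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& X, const mat& WH, double eps) {
  // D(X || WH) = sum( X log(X / WH) - X + WH ), with 0 log 0 := 0
  double d = 0.0;
  for (uword j = 0; j < X.n_cols; ++j) {
    for (uword i = 0; i < X.n_rows; ++i) {
      double x = X(i, j);
      double y = std::max(WH(i, j), eps);
      if (x > 0.0) d += x * std::log(x / y) - x + y;
      else d += y;
    }
  }
  return d;
}

// [[Rcpp::export(name = ".nmf_kl_cpp")]]
Rcpp::List nmf_kl_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      int n_iter, double eps, bool track_loss) {
  const uword m = X.n_rows, n = X.n_cols;
  if (W.n_rows != m || H.n_cols != n || W.n_cols != H.n_rows)
    Rcpp::stop("factor dimensions do not match X");
  vec losses;
  if (track_loss) losses.set_size(n_iter);

  mat WH(m, n), R(m, n);
  for (int it = 0; it < n_iter; ++it) {
    // H update: H <- H * ( W' (X / WH) ) / ( W' 1 )
    WH = W * H;
    WH.transform([eps](double v) { return std::max(v, eps); });
    R = X / WH;
    mat num_h = W.t() * R;                     // r x n
    vec wsum = sum(W, 0).t();                  // column sums of W
    wsum.transform([eps](double v) { return std::max(v, eps); });
    H = H % (num_h.each_col() / wsum);

    // W update: W <- W * ( (X / WH) H' ) / ( 1 H' )
    WH = W * H;
    WH.transform([eps](double v) { return std::max(v, eps); });
    R = X / WH;
    mat num_w = R * H.t();                     // m x r
    rowvec hsum = sum(H, 1).t();               // row sums of H
    hsum.transform([eps](double v) { return std::max(v, eps); });
    W = W % (num_w.each_row() / hsum);

    if (track_loss) {
      WH = W * H;
      losses(it) = kl_div(X, WH, eps);
    }
  }
  double final_loss = track_loss ? losses(n_iter - 1) : kl_div(X, W * H, eps);
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("loss") = final_loss,
    Rcpp::Named("loss_trace") =
      track_loss ? Rcpp::NumericVector(losses.begin(), losses.end())
                 : Rcpp::NumericVector(0));
}
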