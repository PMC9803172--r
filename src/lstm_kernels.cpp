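// Batched LSTM forward / backward kernels.
//
// Layout contract (shared with the R fallback in network.R): inputs for a
// batch of B sequences over p steps are stacked into a (p*B) x h matrix with
// rows (t-1)*B .. t*B-1 holding the batch at step t; gate weight matrices
// stack the forget, input, output and candidate blocks row-wise (4H x h).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& Xbig, int B, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b,
                            bool keep_cache) {
  const int pB = Xbig.n_rows;
  const int p = pB / B;
  const int H = U.n_cols;
  mat XW = Xbig * W.t();
  XW.each_row() += b.t();
  mat Hc(B, H, fill::zeros), Cc(B, H, fill::zeros);
  mat gates, tCs, Cprevs, Hprevs;
  if (keep_cache) {
    gates.set_size(pB, 4 * H);
    tCs.set_size(pB, H);
    Cprevs.set_size(pB, H);
    Hprevs.set_size(pB, H);
  }
  for (int t = 0; t < p; ++t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    mat G = XW.rows(r0, r1) + Hc * U.t();
    mat f = sigm(G.cols(0, H - 1));
    mat i = sigm(G.cols(H, 2 * H - 1));
    mat o = sigm(G.cols(2 * H, 3 * H - 1));
    mat g = tanh(G.cols(3 * H, 4 * H - 1));
    mat Cn = f % Cc + i % g;
    mat tC = tanh(Cn);
    if (keep_cache) {
      gates.submat(r0, 0, r1, H - 1) = f;
      gates.submat(r0, H, r1, 2 * H - 1) = i;
      gates.submat(r0, 2 * H, r1, 3 * H - 1) = o;
      gates.submat(r0, 3 * H, r1, 4 * H - 1) = g;
      tCs.rows(r0, r1) = tC;
      Cprevs.rows(r0, r1) = Cc;
      Hprevs.rows(r0, r1) = Hc;
    }
    Cc = Cn;
    Hc = o % tC;
  }
  if (keep_cache) {
    return Rcpp::List::create(
        Rcpp::Named("h") = Hc,
        Rcpp::Named("cache") = Rcpp::List::create(
            Rcpp::Named("gates") = gates, Rcpp::Named("tC") = tCs,
            Rcpp::Named("Cprev") = Cprevs, Rcpp::Named("Hprev") = Hprevs));
  }
  return Rcpp::List::create(Rcpp::Named("h") = Hc,
                            Rcpp::Named("cache") = R_NilValue);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& dH_final, const arma::mat& Xbig,
                             int B, const arma::mat& U, const arma::mat& gates,
                             const arma::mat& tCs, const arma::mat& Cprevs,
                             const arma::mat& Hprevs) {
  const int pB = Xbig.n_rows;
  const int p = pB / B;
  const int H = dH_final.n_cols;
  mat dGbig(pB, 4 * H);
  mat dH = dH_final;
  mat dC(B, H, fill::zeros);
  for (int t = p - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    mat f = gates.submat(r0, 0, r1, H - 1);
    mat i = gates.submat(r0, H, r1, 2 * H - 1);
    mat o = gates.submat(r0, 2 * H, r1, 3 * H - 1);
    mat g = gates.submat(r0, 3 * H, r1, 4 * H - 1);
    mat tC = tCs.rows(r0, r1);
    mat do_ = dH % tC;
    dC += dH % o % (1.0 - tC % tC);
    mat dG(B, 4 * H);
    dG.cols(0, H - 1) = (dC % Cprevs.rows(r0, r1)) % f % (1.0 - f);
    dG.cols(H, 2 * H - 1) = (dC % g) % i % (1.0 - i);
    dG.cols(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
    dG.cols(3 * H, 4 * H - 1) = (dC % i) % (1.0 - g % g);
    dGbig.rows(r0, r1) = dG;
    dH = dG * U;
    dC %= f;
  }
  return Rcpp::List::create(Rcpp::Named("W") = dGbig.t() * Xbig,
                            Rcpp::Named("U") = dGbig.t() * Hprevs,
                            Rcpp::Named("b") = sum(dGbig, 0).t());
}
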