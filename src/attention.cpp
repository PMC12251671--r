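// Multi-head attention kernels. Activations are (B*T) x d matrices with
// sample-major row blocks; heads are contiguous column blocks of width d/h.
// The R level owns the linear projections; these kernels compute the
// softmax(Q K^T / sqrt(dh)) V core and its backward pass.
//
// To keep the per-sample work in a small number of efficient GEMMs, the
// head loop is folded into block-diagonal forms: with Kblk the d x (h*Tk)
// matrix holding head hh's K^T in row-block hh / column-block hh (zeros
// elsewhere), Q * Kblk yields all head score matrices side by side in one
// product, and A_all * Vblk recovers the concatenated head outputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".att_core_fwd")]]
Rcpp::List att_core_fwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                        int B, int Tq, int Tk, int h) {
  const int d = Q.n_cols;
  const int dh = d / h;
  const double scal = 1.0 / std::sqrt((double) dh);
  mat O(B * Tq, d, fill::none);
  cube A(Tq, (uword) Tk * h, B, fill::none);
  mat Kblk(d, (uword) Tk * h, fill::zeros);
  mat Vblk((uword) Tk * h, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword rq0 = (uword) b * Tq, rq1 = rq0 + Tq - 1;
    const uword rk0 = (uword) b * Tk, rk1 = rk0 + Tk - 1;
    for (int hh = 0; hh < h; ++hh) {
      const uword c0 = (uword) hh * dh, c1 = c0 + dh - 1;
      const uword k0 = (uword) hh * Tk, k1 = k0 + Tk - 1;
      Kblk.submat(c0, k0, c1, k1) = K.submat(rk0, c0, rk1, c1).t();
      Vblk.submat(k0, c0, k1, c1) = V.submat(rk0, c0, rk1, c1);
    }
    mat S = Q.rows(rq0, rq1) * Kblk;           // Tq x (h*Tk), heads side by side
    S *= scal;
    for (int hh = 0; hh < h; ++hh) {
      const uword k0 = (uword) hh * Tk, k1 = k0 + Tk - 1;
      mat Sh = S.cols(k0, k1);
      Sh.each_col() -= max(Sh, 1);
      Sh = exp(Sh);
      Sh.each_col() /= sum(Sh, 1);
      S.cols(k0, k1) = Sh;
    }
    O.rows(rq0, rq1) = S * Vblk;               // block-diagonal gather
    A.slice(b) = S;
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// [[Rcpp::export(name = ".att_core_bwd")]]
Rcpp::List att_core_bwd(const arma::mat& dO, const arma::cube& A, const arma::mat& Q,
                        const arma::mat& K, const arma::mat& V,
                        int B, int Tq, int Tk, int h) {
  const int d = Q.n_cols;
  const int dh = d / h;
  const double scal = 1.0 / std::sqrt((double) dh);
  mat dQ(B * Tq, d, fill::none);
  mat dK(B * Tk, d, fill::none);
  mat dV(B * Tk, d, fill::none);
  mat Kblk(d, (uword) Tk * h, fill::zeros);
  mat Vblk((uword) Tk * h, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword rq0 = (uword) b * Tq, rq1 = rq0 + Tq - 1;
    const uword rk0 = (uword) b * Tk, rk1 = rk0 + Tk - 1;
    for (int hh = 0; hh < h; ++hh) {
      const uword c0 = (uword) hh * dh, c1 = c0 + dh - 1;
      const uword k0 = (uword) hh * Tk, k1 = k0 + Tk - 1;
      Kblk.submat(c0, k0, c1, k1) = K.submat(rk0, c0, rk1, c1).t();
      Vblk.submat(k0, c0, k1, c1) = V.submat(rk0, c0, rk1, c1);
    }
    const mat& Ab = A.slice(b);                 // Tq x (h*Tk)
    mat dA = dO.rows(rq0, rq1) * Vblk.t();      // Tq x (h*Tk), per-head blocks
    mat dVb = Ab.t() * dO.rows(rq0, rq1);       // (h*Tk) x d, block rows
    mat dS = Ab % dA;
    for (int hh = 0; hh < h; ++hh) {
      const uword k0 = (uword) hh * Tk, k1 = k0 + Tk - 1;
      const uword c0 = (uword) hh * dh, c1 = c0 + dh - 1;
      vec rs = sum(dS.cols(k0, k1), 1);
      mat Ah = Ab.cols(k0, k1);
      Ah.each_col() %= rs;
      dS.cols(k0, k1) -= Ah;
      dV.submat(rk0, c0, rk1, c1) = dVb.submat(k0, c0, k1, c1);
    }
    dS *= scal;
    dQ.rows(rq0, rq1) = dS * Kblk.t();          // block-diagonal gather
    mat dKb = dS.t() * Q.rows(rq0, rq1);        // (h*Tk) x d
    for (int hh = 0; hh < h; ++hh) {
      const uword k0 = (uword) hh * Tk, k1 = k0 + Tk - 1;
      const uword c0 = (uword) hh * dh, c1 = c0 + dh - 1;
      dK.submat(rk0, c0, rk1, c1) = dKb.submat(k0, c0, k1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// Row-wise layer normalization over the feature dimension.

// [[Rcpp::export(name = ".ln_fwd")]]
Rcpp::List ln_fwd_cpp(const arma::mat& X, const arma::vec& g, const arma::vec& b) {
  vec mu = mean(X, 1);
  mat xc = X;
  xc.each_col() -= mu;
  vec inv = 1.0 / sqrt(mean(xc % xc, 1) + 1e-5);
  xc.each_col() %= inv;                 // xc is now xh
  mat Y = xc;
  Y.each_row() %= g.t();
  Y.each_row() += b.t();
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("xh") = xc,
                            Rcpp::Named("inv") = inv);
}

// [[Rcpp::export(name = ".ln_bwd")]]
Rcpp::List ln_bwd_cpp(const arma::mat& dY, const arma::mat& xh,
                      const arma::vec& inv, const arma::vec& g) {
  mat dxh = dY;
  dxh.each_row() %= g.t();
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % xh, 1);
  mat dX = dxh;
  dX.each_col() -= m1;
  mat xm = xh;
  xm.each_col() %= m2;
  dX -= xm;
  dX.each_col() %= inv;
  return Rcpp::List::create(
    Rcpp::Named("dX") = dX,
    Rcpp::Named("g") = sum(dY % xh, 0).t(),
    Rcpp::Named("b") = sum(dY, 0).t());
}
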