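#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// 3x3 same-padding convolutions via im2col + GEMM.
// Tensors are (H, W, C) cubes; weights are (Cout x Cin*9) matrices with
// column index c*9 + kr*3 + kc (0-based kernel row kr, kernel col kc).

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat col(C * 9, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int kr = 0; kr < 3; ++kr) {
      for (int kc = 0; kc < 3; ++kc) {
        const int r = c * 9 + kr * 3 + kc;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kc - 1;
          if (sj < 0 || sj >= W) continue;
          const int i0 = (kr - 1 < 0) ? 1 : 0;        // first output row with valid source
          const int i1 = (kr - 1 > 0) ? H - 1 : H;    // one past last
          for (int i = i0; i < i1; ++i) {
            col(r, i + j * H) = x(i + kr - 1, sj, c);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube conv3x3_fwd(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  mat col = im2col3(x);
  mat y = w * col;               // Cout x (H*W)
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = reshape(y.row(o), H, W);
  return out;
}

// [[Rcpp::export]]
arma::cube conv3x3_bwd_input(const arma::cube& dy, const arma::mat& w) {
  const int H = dy.n_rows, W = dy.n_cols, Cout = dy.n_slices;
  const int Cin = w.n_cols / 9;
  mat dym(Cout, H * W);
  for (int o = 0; o < Cout; ++o)
    dym.row(o) = vectorise(dy.slice(o)).t();
  mat dcol = w.t() * dym;        // (Cin*9) x (H*W)
  cube dx(H, W, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int kr = 0; kr < 3; ++kr) {
      for (int kc = 0; kc < 3; ++kc) {
        const int r = c * 9 + kr * 3 + kc;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kc - 1;
          if (sj < 0 || sj >= W) continue;
          const int i0 = (kr - 1 < 0) ? 1 : 0;
          const int i1 = (kr - 1 > 0) ? H - 1 : H;
          for (int i = i0; i < i1; ++i) {
            dx(i + kr - 1, sj, c) += dcol(r, i + j * H);
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_bwd_wb(const arma::cube& x, const arma::cube& dy) {
  const int H = dy.n_rows, W = dy.n_cols, Cout = dy.n_slices;
  mat dym(Cout, H * W);
  for (int o = 0; o < Cout; ++o)
    dym.row(o) = vectorise(dy.slice(o)).t();
  mat col = im2col3(x);
  mat dw = dym * col.t();        // Cout x (Cin*9)
  vec db = sum(dym, 1);
  return Rcpp::List::create(Rcpp::Named("dw") = dw, Rcpp::Named("db") = db);
}
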