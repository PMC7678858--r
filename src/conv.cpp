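// Same-padded 2D convolution layers for the phase-unwrapping network,
// implemented as im2col + GEMM. Layouts: input/output cubes are
// (H, W, channels); the weight matrix is (C_out, k*k*C_in) with column
// order (dy, dx, c_in) fastest-to-slowest matching im2col below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat im2col(const cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& sl = x.slice(c);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int row = c * k * k + dx * k + dy;
        // source pixel (i + dy - p, j + dx - p) for output pixel (i, j)
        const int oy = dy - p, ox = dx - p;
        const int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
        const int j0 = std::max(0, -ox), j1 = std::min(W, W - ox);
        for (int j = j0; j < j1; ++j) {
          const double* src = sl.colptr(j + ox);
          double* dst = cols.memptr();
          for (int i = i0; i < i1; ++i) {
            dst[row + (size_t)(j * H + i) * cols.n_rows] = src[i + oy];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(cube& x, const mat& cols, const int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    mat& sl = x.slice(c);
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const int row = c * k * k + dx * k + dy;
        const int oy = dy - p, ox = dx - p;
        const int i0 = std::max(0, -oy), i1 = std::min(H, H - oy);
        const int j0 = std::max(0, -ox), j1 = std::min(W, W - ox);
        for (int j = j0; j < j1; ++j) {
          double* dst = sl.colptr(j + ox);
          const double* src = cols.memptr();
          for (int i = i0; i < i1; ++i) {
            dst[i + oy] += src[row + (size_t)(j * H + i) * cols.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& input, const arma::mat& weights,
                      const arma::vec& bias, const int k) {
  const int H = input.n_rows, W = input.n_cols;
  const int cout = weights.n_rows;
  mat cols = im2col(input, k);
  mat out = weights * cols;           // (C_out, H*W)
  out.each_col() += bias;
  cube y(H, W, cout);
  for (int c = 0; c < cout; ++c) {
    y.slice(c) = reshape(out.row(c), H, W);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& input, const arma::mat& weights,
                      const int k, const arma::cube& gout) {
  const int H = input.n_rows, W = input.n_cols;
  const int cin = input.n_slices, cout = gout.n_slices;
  mat g(cout, H * W);
  for (int c = 0; c < cout; ++c) {
    g.row(c) = vectorise(gout.slice(c)).t();
  }
  mat cols = im2col(input, k);
  mat dW = g * cols.t();              // (C_out, k*k*C_in)
  vec db = sum(g, 1);
  mat dcols = weights.t() * g;        // (k*k*C_in, H*W)
  cube dx(H, W, cin, fill::zeros);
  col2im_add(dx, dcols, k);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
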