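// Low-level numerical kernels for the 1D CNN engine.
//
// Layout convention: a batch is an arma::cube of dimension
// (channels x length x records).  Convolutions use "same" padding:
// out_len = ceil(len / stride), zeros implied outside the signal.
// All randomness (dropout) is drawn from R's RNG so seeded R sessions
// reproduce training runs bit for bit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_len_same(int L, int stride) {
  return (L + stride - 1) / stride;
}

static inline int pad_left_same(int L, int m, int stride) {
  int Lo = out_len_same(L, stride);
  int pad_total = (Lo - 1) * stride + m - L;
  if (pad_total < 0) pad_total = 0;
  return pad_total / 2;
}

// im2col for one record: (Cin x L) -> (Cin*m x Lout)
static void im2col(const arma::mat& x, int m, int stride, arma::mat& col) {
  const int Cin = x.n_rows, L = x.n_cols;
  const int Lo = out_len_same(L, stride);
  const int pl = pad_left_same(L, m, stride);
  col.zeros(Cin * m, Lo);
  if (stride == 1) {
    // per-tap contiguous block copy: output t reads input t + j - pl
    for (int j = 0; j < m; ++j) {
      const int shift = j - pl;
      const int src_lo = std::max(0, shift);
      const int src_hi = std::min(L - 1, L - 1 + shift);
      const int t_lo = src_lo - shift, t_hi = src_hi - shift;
      if (t_lo > t_hi) continue;
      col.submat(j * Cin, t_lo, (j + 1) * Cin - 1, t_hi) =
        x.cols(src_lo, src_hi);
    }
    return;
  }
  for (int t = 0; t < Lo; ++t) {
    const int start = t * stride - pl;
    for (int j = 0; j < m; ++j) {
      const int src = start + j;
      if (src < 0 || src >= L) continue;
      col.submat(j * Cin, t, (j + 1) * Cin - 1, t) = x.col(src);
    }
  }
}

// scatter-add of column gradient back to the input: inverse of im2col
static void col2im(const arma::mat& dcol, int Cin, int L, int m, int stride,
                   arma::mat& dx) {
  const int Lo = out_len_same(L, stride);
  const int pl = pad_left_same(L, m, stride);
  dx.zeros(Cin, L);
  if (stride == 1) {
    for (int j = 0; j < m; ++j) {
      const int shift = j - pl;
      const int src_lo = std::max(0, shift);
      const int src_hi = std::min(L - 1, L - 1 + shift);
      const int t_lo = src_lo - shift, t_hi = src_hi - shift;
      if (t_lo > t_hi) continue;
      dx.cols(src_lo, src_hi) +=
        dcol.submat(j * Cin, t_lo, (j + 1) * Cin - 1, t_hi);
    }
    return;
  }
  for (int t = 0; t < Lo; ++t) {
    const int start = t * stride - pl;
    for (int j = 0; j < m; ++j) {
      const int src = start + j;
      if (src < 0 || src >= L) continue;
      dx.col(src) += dcol.submat(j * Cin, t, (j + 1) * Cin - 1, t);
    }
  }
}

// records per im2col chunk, bounding the scratch matrix near 64 MB
static int conv_chunk(int Cin, int m, int Lo, int N) {
  const double per_slice = (double)Cin * m * Lo;
  int chunk = (int)(8.0e6 / std::max(per_slice, 1.0));
  if (chunk < 1) chunk = 1;
  if (chunk > N) chunk = N;
  return chunk;
}

// W is (Cout x Cin*m), kernel tap j and input channel c at row index c + j*Cin.
// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int m, int stride,
                          bool use_bias) {
  const int Cin = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int Cout = W.n_rows;
  const int Lo = out_len_same(L, stride);
  arma::cube y(Cout, Lo, N);
  const int chunk = conv_chunk(Cin, m, Lo, N);
  arma::mat col_all(Cin * m, (size_t)Lo * chunk);
  arma::mat coln;
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nc = std::min(chunk, N - n0);
    for (int j = 0; j < nc; ++j) {
      im2col(x.slice(n0 + j), m, stride, coln);
      col_all.cols((size_t)j * Lo, (size_t)(j + 1) * Lo - 1) = coln;
    }
    arma::mat out(y.slice_memptr(n0), Cout, (size_t)Lo * nc, false, true);
    out = W * col_all.cols(0, (size_t)nc * Lo - 1);
    if (use_bias) out.each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(const arma::cube& x, const arma::mat& W,
                    const arma::cube& dy, int m, int stride, bool use_bias) {
  const int Cin = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int Cout = W.n_rows;
  const int Lo = dy.n_cols;
  arma::cube dx(Cin, L, N);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(W.n_rows, arma::fill::zeros);
  const int chunk = conv_chunk(Cin, m, Lo, N);
  arma::mat col_all(Cin * m, (size_t)Lo * chunk);
  arma::mat coln, dcol_all, dxs;
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nc = std::min(chunk, N - n0);
    for (int j = 0; j < nc; ++j) {
      im2col(x.slice(n0 + j), m, stride, coln);
      col_all.cols((size_t)j * Lo, (size_t)(j + 1) * Lo - 1) = coln;
    }
    const arma::mat dym(const_cast<double*>(dy.slice_memptr(n0)), Cout,
                        (size_t)Lo * nc, false, true);
    dW += dym * col_all.cols(0, (size_t)nc * Lo - 1).t();
    dcol_all = W.t() * dym;
    for (int j = 0; j < nc; ++j) {
      col2im(dcol_all.cols((size_t)j * Lo, (size_t)(j + 1) * Lo - 1),
             Cin, L, m, stride, dxs);
      dx.slice(n0 + j) = dxs;
    }
    if (use_bias) db += arma::sum(dym, 1);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Non-overlapping max pooling, window = stride = P; trailing remainder
// dropped. Operates on the flat (C x L x N) array without copies; the
// returned idx holds flat 0-based winner positions into x.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector dims, int P) {
  const int C = dims[0], L = dims[1], N = dims[2];
  const int Lo = L / P;
  NumericVector y(C * Lo * N);
  IntegerVector idx(C * Lo * N);
  const double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    const R_xlen_t base_in = (R_xlen_t)n * C * L;
    const R_xlen_t base_out = (R_xlen_t)n * C * Lo;
    for (int t = 0; t < Lo; ++t) {
      for (int c = 0; c < C; ++c) {
        R_xlen_t best = base_in + (R_xlen_t)(t * P) * C + c;
        double bv = px[best];
        for (int j = 1; j < P; ++j) {
          const R_xlen_t k = base_in + (R_xlen_t)(t * P + j) * C + c;
          if (px[k] > bv) { bv = px[k]; best = k; }
        }
        const R_xlen_t o = base_out + (R_xlen_t)t * C + c;
        y[o] = bv;
        idx[o] = (int)best;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, Lo, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              int C, int L, int N) {
  NumericVector dx((R_xlen_t)C * L * N);
  for (R_xlen_t i = 0; i < idx.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = IntegerVector::create(C, L, N);
  return dx;
}

// Channel-wise batch normalization over (length x records); x is the flat
// (C x L x N) array, channel index fastest.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, IntegerVector dims, NumericVector gamma,
                NumericVector beta, NumericVector rmean, NumericVector rvar,
                double momentum, double eps, bool training) {
  const int C = dims[0];
  const R_xlen_t ncol = x.size() / C;
  NumericVector mean(C), var(C);
  const double* px = x.begin();
  if (training) {
    const double denom = (double)ncol;
    for (R_xlen_t j = 0; j < ncol; ++j) {
      const double* base = px + j * C;
      for (int c = 0; c < C; ++c) mean[c] += base[c];
    }
    for (int c = 0; c < C; ++c) mean[c] /= denom;
    for (R_xlen_t j = 0; j < ncol; ++j) {
      const double* base = px + j * C;
      for (int c = 0; c < C; ++c) {
        const double d = base[c] - mean[c];
        var[c] += d * d;
      }
    }
    for (int c = 0; c < C; ++c) var[c] /= denom;  // biased, as normalized
  } else {
    mean = clone(rmean);
    var = clone(rvar);
  }
  std::vector<double> scale(C), shift(C);
  for (int c = 0; c < C; ++c) {
    scale[c] = gamma[c] / std::sqrt(var[c] + eps);
    shift[c] = beta[c] - mean[c] * scale[c];
  }
  NumericVector y(x.size());
  double* py = y.begin();
  for (R_xlen_t j = 0; j < ncol; ++j) {
    const double* base = px + j * C;
    double* out = py + j * C;
    for (int c = 0; c < C; ++c) out[c] = base[c] * scale[c] + shift[c];
  }
  y.attr("dim") = dims;
  NumericVector new_rmean = clone(rmean), new_rvar = clone(rvar);
  if (training)
    for (int c = 0; c < C; ++c) {
      new_rmean[c] = (1.0 - momentum) * rmean[c] + momentum * mean[c];
      new_rvar[c] = (1.0 - momentum) * rvar[c] + momentum * var[c];
    }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector x, NumericVector dy, IntegerVector dims,
                NumericVector gamma, NumericVector mean, NumericVector var,
                double eps) {
  const int C = dims[0];
  const R_xlen_t ncol = x.size() / C;
  const double M = (double)ncol;
  std::vector<double> inv_sd(C);
  for (int c = 0; c < C; ++c) inv_sd[c] = 1.0 / std::sqrt(var[c] + eps);
  NumericVector dgamma(C), dbeta(C);
  const double* px = x.begin();
  const double* pdy = dy.begin();
  for (R_xlen_t j = 0; j < ncol; ++j) {
    const double* bx = px + j * C;
    const double* bdy = pdy + j * C;
    for (int c = 0; c < C; ++c) {
      dbeta[c] += bdy[c];
      dgamma[c] += bdy[c] * (bx[c] - mean[c]) * inv_sd[c];
    }
  }
  NumericVector dx(x.size());
  double* pdx = dx.begin();
  for (R_xlen_t j = 0; j < ncol; ++j) {
    const double* bx = px + j * C;
    const double* bdy = pdy + j * C;
    double* bdx = pdx + j * C;
    for (int c = 0; c < C; ++c) {
      const double xh = (bx[c] - mean[c]) * inv_sd[c];
      bdx[c] = gamma[c] * inv_sd[c] / M *
        (M * bdy[c] - dbeta[c] - xh * dgamma[c]);
    }
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector y, NumericVector dy) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (y[i] <= 0) dx[i] = 0;
  return dx;
}

// Inverted dropout; mask drawn from R's RNG stream.
// [[Rcpp::export]]
List cpp_dropout_fwd(NumericVector x, double rate) {
  RNGScope scope;
  const double keep = 1.0 - rate;
  NumericVector y(x.size()), mask(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double m = (unif_rand() < keep) ? 1.0 / keep : 0.0;
    mask[i] = m;
    y[i] = x[i] * m;
  }
  y.attr("dim") = x.attr("dim");
  mask.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mask"] = mask);
}
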