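// Minimal 1D neural-network kernels used by the residual backbone.
//
// Layout convention (column-major friendly):
//   activations: cube (L, C, N)  -- length x channels x batch
//   conv weight: cube (K, Cin, Cout), flattened to (K*Cin, Cout) for GEMM
// Convolutions are implemented as batched im2col + one GEMM per call (the
// whole minibatch shares a single matrix multiply, which matters at desk
// scale where per-sample GEMMs are overhead-bound). Backward scatters
// with col2im. All kernels are single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int conv_out_len(int L, int K, int stride, int pad) {
  return (L + 2 * pad - K) / stride + 1;
}

// Fill rows [n*Lout, (n+1)*Lout) of the batched im2col matrix
// M ((N*Lout) x K*Cin) from sample n. Column index is c*K + k so the
// flattened weight cube (K, Cin, Cout) matches.
static void im2col_into(const mat& x, int K, int stride, int pad,
                        int Lout, int row0, mat& M) {
  const int L = x.n_rows, C = x.n_cols;
  for (int c = 0; c < C; ++c) {
    const double* src = x.colptr(c);
    for (int k = 0; k < K; ++k) {
      double* dst = M.colptr(c * K + k) + row0;
      for (int l = 0; l < Lout; ++l) {
        int t = l * stride + k - pad;
        dst[l] = (t >= 0 && t < L) ? src[t] : 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fwd(const arma::cube& x, const arma::cube& w,
                          const arma::vec& b, int stride, int pad) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int K = w.n_rows, Cin = w.n_cols, Cout = w.n_slices;
  if (Cin != C) Rcpp::stop("conv1d: channel mismatch");
  const int Lout = conv_out_len(L, K, stride, pad);
  if (Lout < 1) Rcpp::stop("conv1d: output length < 1");
  const mat Wmat(const_cast<double*>(w.memptr()), K * Cin, Cout, false, true);
  mat M(N * Lout, K * Cin);
  for (int n = 0; n < N; ++n)
    im2col_into(x.slice(n), K, stride, pad, Lout, n * Lout, M);
  mat Y = M * Wmat;              // (N*Lout) x Cout
  Y.each_row() += b.t();
  cube y(Lout, Cout, N);
  for (int n = 0; n < N; ++n)
    y.slice(n) = Y.rows(n * Lout, (n + 1) * Lout - 1);
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bwd(const arma::cube& x, const arma::cube& w,
                          const arma::cube& gy, int stride, int pad) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int K = w.n_rows, Cout = w.n_slices;
  const int Lout = gy.n_rows;
  const mat Wmat(const_cast<double*>(w.memptr()), K * C, Cout, false, true);
  mat M(N * Lout, K * C);
  for (int n = 0; n < N; ++n)
    im2col_into(x.slice(n), K, stride, pad, Lout, n * Lout, M);
  mat GY(N * Lout, Cout);
  for (int n = 0; n < N; ++n)
    GY.rows(n * Lout, (n + 1) * Lout - 1) = gy.slice(n);
  mat gW = M.t() * GY;           // (K*C) x Cout
  vec gb = sum(GY, 0).t();
  mat gM = GY * Wmat.t();        // (N*Lout) x K*C
  cube gx(L, C, N, fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat& gxs = gx.slice(n);
    for (int c = 0; c < C; ++c) {
      double* dst = gxs.colptr(c);
      for (int k = 0; k < K; ++k) {
        const double* src = gM.colptr(c * K + k) + n * Lout;
        for (int l = 0; l < Lout; ++l) {
          int t = l * stride + k - pad;
          if (t >= 0 && t < L) dst[t] += src[l];
        }
      }
    }
  }
  cube gw(gW.memptr(), K, C, Cout);
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool1d_fwd(const arma::cube& x, int K, int stride, int pad) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int Lout = conv_out_len(L, K, stride, pad);
  cube y(Lout, C, N);
  icube idx(Lout, C, N);  // 0-based source index of the max
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* src = x.slice(n).colptr(c);
      for (int l = 0; l < Lout; ++l) {
        double best = -datum::inf; int bi = -1;
        for (int k = 0; k < K; ++k) {
          int t = l * stride + k - pad;
          if (t >= 0 && t < L && src[t] > best) { best = src[t]; bi = t; }
        }
        y(l, c, n) = best;
        idx(l, c, n) = bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool1d_bwd(const arma::icube& idx, const arma::cube& gy, int Lin) {
  const int Lout = gy.n_rows, C = gy.n_cols, N = gy.n_slices;
  cube gx(Lin, C, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int l = 0; l < Lout; ++l)
        gx(idx(l, c, n), c, n) += gy(l, c, n);
  return gx;
}

// Group normalization over (length x channels-in-group) per sample.
// [[Rcpp::export]]
Rcpp::List cpp_groupnorm_fwd(const arma::cube& x, const arma::vec& gamma,
                             const arma::vec& beta, int groups, double eps) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  if (C % groups != 0) Rcpp::stop("groupnorm: channels not divisible by groups");
  const int Cg = C / groups;
  cube y(L, C, N);
  mat mu(groups, N), invstd(groups, N);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      const mat sub = x.slice(n).cols(g * Cg, (g + 1) * Cg - 1);
      double m = accu(sub) / (L * Cg);
      double v = accu(square(sub - m)) / (L * Cg);
      double is = 1.0 / std::sqrt(v + eps);
      mu(g, n) = m; invstd(g, n) = is;
      for (int j = 0; j < Cg; ++j) {
        int c = g * Cg + j;
        y.slice(n).col(c) = (x.slice(n).col(c) - m) * is * gamma(c) + beta(c);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("mu") = mu,
                            Rcpp::Named("invstd") = invstd);
}

// [[Rcpp::export]]
Rcpp::List cpp_groupnorm_bwd(const arma::cube& x, const arma::vec& gamma,
                             const arma::cube& gy, const arma::mat& mu,
                             const arma::mat& invstd, int groups) {
  const int L = x.n_rows, C = x.n_cols, N = x.n_slices;
  const int Cg = C / groups;
  const double m = (double)L * Cg;
  cube gx(L, C, N);
  vec ggamma(C, fill::zeros), gbeta(C, fill::zeros);
  for (int n = 0; n < N; ++n) {
    for (int g = 0; g < groups; ++g) {
      double is = invstd(g, n), cmu = mu(g, n);
      double s1 = 0.0, s2 = 0.0;  // mean(dxhat), mean(dxhat*xhat)
      for (int j = 0; j < Cg; ++j) {
        int c = g * Cg + j;
        const vec xhat = (x.slice(n).col(c) - cmu) * is;
        const vec dxh = gamma(c) * gy.slice(n).col(c);
        s1 += accu(dxh);
        s2 += accu(dxh % xhat);
        ggamma(c) += accu(gy.slice(n).col(c) % xhat);
        gbeta(c) += accu(gy.slice(n).col(c));
      }
      s1 /= m; s2 /= m;
      for (int j = 0; j < Cg; ++j) {
        int c = g * Cg + j;
        const vec xhat = (x.slice(n).col(c) - cmu) * is;
        const vec dxh = gamma(c) * gy.slice(n).col(c);
        gx.slice(n).col(c) = (dxh - s1 - xhat * s2) * is;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}
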