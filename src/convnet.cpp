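// Compiled primitives for the 3D convolutional conditioning encoder.
//
// Activation layout: a batch is a dense matrix with one column per sample and
// (n_channels * n_voxels) rows, channel-fastest (row = channel + C * voxel).
// Convolutions are expressed as im2col gathers against a precomputed neighbour
// table `nbr` (K x n_out, 0-based input voxel ids, -1 = zero padding) followed
// by a GEMM against a weight matrix W of shape (C_out x K*C_in), whose columns
// are ordered channel-fastest within each kernel offset.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static void im2col(const double* a, const IntegerMatrix& nbr, int Cin,
                   arma::mat& G) {
  const int K = nbr.nrow(), npos = nbr.ncol();
  for (int p = 0; p < npos; ++p) {
    double* g = G.colptr(p);
    for (int k = 0; k < K; ++k) {
      const int v = nbr(k, p);
      if (v < 0) {
        std::fill(g + k * Cin, g + (k + 1) * Cin, 0.0);
      } else {
        const double* src = a + static_cast<size_t>(v) * Cin;
        std::copy(src, src + Cin, g + k * Cin);
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& A, const IntegerMatrix& nbr,
                         const arma::mat& W, const arma::vec& b, int Cin) {
  const int K = nbr.nrow(), npos = nbr.ncol(), B = A.n_cols;
  const int Cout = W.n_rows;
  if ((int)W.n_cols != K * Cin) stop("conv weight shape mismatch");
  if ((int)A.n_rows % Cin != 0) stop("activation rows not divisible by Cin");
  arma::mat Y(static_cast<size_t>(Cout) * npos, B);
  arma::mat G(static_cast<size_t>(K) * Cin, npos);
  for (int s = 0; s < B; ++s) {
    im2col(A.colptr(s), nbr, Cin, G);
    arma::mat Ys = W * G;  // Cout x npos
    Ys.each_col() += b;
    std::memcpy(Y.colptr(s), Ys.memptr(),
                sizeof(double) * static_cast<size_t>(Cout) * npos);
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& A, const IntegerMatrix& nbr,
                    const arma::mat& W, const arma::mat& dY, int Cin,
                    bool need_dA) {
  const int K = nbr.nrow(), npos = nbr.ncol(), B = A.n_cols;
  const int Cout = W.n_rows;
  if ((int)dY.n_rows != Cout * npos || (int)dY.n_cols != B)
    stop("conv gradient shape mismatch");
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dA;
  if (need_dA) dA.zeros(A.n_rows, B);
  arma::mat G(static_cast<size_t>(K) * Cin, npos);
  for (int s = 0; s < B; ++s) {
    im2col(A.colptr(s), nbr, Cin, G);
    const arma::mat dYs(const_cast<double*>(dY.colptr(s)), Cout, npos,
                        false, true);
    dW += dYs * G.t();
    db += arma::sum(dYs, 1);
    if (need_dA) {
      arma::mat dG = W.t() * dYs;  // (K*Cin) x npos
      double* das = dA.colptr(s);
      for (int p = 0; p < npos; ++p) {
        const double* g = dG.colptr(p);
        for (int k = 0; k < K; ++k) {
          const int v = nbr(k, p);
          if (v >= 0) {
            double* dst = das + static_cast<size_t>(v) * Cin;
            for (int c = 0; c < Cin; ++c) dst[c] += g[k * Cin + c];
          }
        }
      }
    }
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// Batch normalization over all spatial positions and samples of each channel,
// fused with ReLU. `Y` has (C * npos) rows; statistics are per channel.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(const arma::mat& Y, int C, const arma::vec& gamma,
                     const arma::vec& beta, const arma::vec& mean_in,
                     const arma::vec& var_in, bool use_given_stats,
                     double eps) {
  const size_t R = Y.n_rows, B = Y.n_cols;
  const size_t npos = R / C;
  arma::vec mu(C), var(C);
  if (use_given_stats) {
    mu = mean_in;
    var = var_in;
  } else {
    mu.zeros();
    var.zeros();
    const double N = static_cast<double>(npos * B);
    for (size_t s = 0; s < B; ++s) {
      const double* y = Y.colptr(s);
      for (size_t v = 0; v < npos; ++v) {
        const double* yv = y + v * C;
        for (int c = 0; c < C; ++c) {
          mu[c] += yv[c];
          var[c] += yv[c] * yv[c];
        }
      }
    }
    mu /= N;
    var = var / N - mu % mu;
    var.transform([](double v) { return v < 0 ? 0.0 : v; });
  }
  arma::vec invstd = 1.0 / arma::sqrt(var + eps);
  arma::mat xhat(R, B), out(R, B);
  for (size_t s = 0; s < B; ++s) {
    const double* y = Y.colptr(s);
    double* xh = xhat.colptr(s);
    double* o = out.colptr(s);
    for (size_t v = 0; v < npos; ++v) {
      const size_t base = v * C;
      for (int c = 0; c < C; ++c) {
        const double z = (y[base + c] - mu[c]) * invstd[c];
        xh[base + c] = z;
        const double a = gamma[c] * z + beta[c];
        o[base + c] = a > 0 ? a : 0.0;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mean"] = mu,
                      _["var"] = var, _["invstd"] = invstd);
}

// Backward pass for batch-norm + ReLU (batch-statistics mode).
// [[Rcpp::export]]
List cpp_bn_relu_bwd(const arma::mat& dOut, const arma::mat& out,
                     const arma::mat& xhat, const arma::vec& gamma,
                     const arma::vec& invstd, int C) {
  const size_t R = dOut.n_rows, B = dOut.n_cols;
  const size_t npos = R / C;
  const double N = static_cast<double>(npos * B);
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  // First pass: relu-masked upstream gradient and per-channel sums.
  arma::mat dZ(R, B);
  for (size_t s = 0; s < B; ++s) {
    const double* dq = dOut.colptr(s);
    const double* o = out.colptr(s);
    const double* xh = xhat.colptr(s);
    double* dz = dZ.colptr(s);
    for (size_t v = 0; v < npos; ++v) {
      const size_t base = v * C;
      for (int c = 0; c < C; ++c) {
        const double g = o[base + c] > 0 ? dq[base + c] : 0.0;
        dz[base + c] = g;
        dbeta[c] += g;
        dgamma[c] += g * xh[base + c];
      }
    }
  }
  arma::mat dY(R, B);
  arma::vec scale = gamma % invstd / N;
  for (size_t s = 0; s < B; ++s) {
    const double* dz = dZ.colptr(s);
    const double* xh = xhat.colptr(s);
    double* dy = dY.colptr(s);
    for (size_t v = 0; v < npos; ++v) {
      const size_t base = v * C;
      for (int c = 0; c < C; ++c)
        dy[base + c] = scale[c] *
          (N * dz[base + c] - dbeta[c] - xh[base + c] * dgamma[c]);
    }
  }
  return List::create(_["dY"] = dY, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
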