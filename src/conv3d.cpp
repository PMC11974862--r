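// 3D convolution primitives for the residual encoder.
//
// Volumes are stored channel-first in column-major R arrays with
// dim = (C, X, Y, Z), so index = c + C*(x + X*(y + Y*z)).  Weights for a
// layer with kernel size K are a (Cout x Cin*K^3) matrix whose column index
// is cin + Cin*(kx + K*(ky + K*kz)).  Convolutions use zero padding
// (K-1)/2 and an integer stride; forward and backward are implemented as
// im2col + GEMM so they run on BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int n, int k, int pad, int stride) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix: rows Cin*K^3, cols = number of output voxels.
static void im2col(const double* x, int C, int X, int Y, int Z,
                   int K, int pad, int stride,
                   int OX, int OY, int OZ, arma::mat& cols) {
  const int K3 = K * K * K;
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int col = ox + OX * (oy + OY * oz);
        double* dst = cols.colptr(col);
        for (int kz = 0; kz < K; ++kz) {
          const int z = oz * stride - pad + kz;
          for (int ky = 0; ky < K; ++ky) {
            const int y = oy * stride - pad + ky;
            for (int kx = 0; kx < K; ++kx) {
              const int xx = ox * stride - pad + kx;
              double* d = dst + C * (kx + K * (ky + K * kz));
              if (xx < 0 || xx >= X || y < 0 || y >= Y || z < 0 || z >= Z) {
                for (int c = 0; c < C; ++c) d[c] = 0.0;
              } else {
                const double* s = x + C * (xx + X * (y + Y * z));
                for (int c = 0; c < C; ++c) d[c] = s[c];
              }
            }
          }
        }
      }
    }
  }
  (void)K3;
}

// Scatter-add of im2col columns back into a gradient volume.
static void col2im(const arma::mat& cols, int C, int X, int Y, int Z,
                   int K, int pad, int stride,
                   int OX, int OY, int OZ, double* gx) {
  std::fill(gx, gx + (size_t)C * X * Y * Z, 0.0);
  for (int oz = 0; oz < OZ; ++oz) {
    for (int oy = 0; oy < OY; ++oy) {
      for (int ox = 0; ox < OX; ++ox) {
        const int col = ox + OX * (oy + OY * oz);
        const double* src = cols.colptr(col);
        for (int kz = 0; kz < K; ++kz) {
          const int z = oz * stride - pad + kz;
          if (z < 0 || z >= Z) continue;
          for (int ky = 0; ky < K; ++ky) {
            const int y = oy * stride - pad + ky;
            if (y < 0 || y >= Y) continue;
            for (int kx = 0; kx < K; ++kx) {
              const int xx = ox * stride - pad + kx;
              if (xx < 0 || xx >= X) continue;
              const double* s = src + C * (kx + K * (ky + K * kz));
              double* d = gx + C * (xx + X * (y + Y * z));
              for (int c = 0; c < C; ++c) d[c] += s[c];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3dForward")]]
NumericVector conv3dForward(NumericVector input, NumericMatrix weight,
                            NumericVector bias, int stride, int ksize) {
  IntegerVector dm = input.attr("dim");
  const int C = dm[0], X = dm[1], Y = dm[2], Z = dm[3];
  const int pad = (ksize - 1) / 2;
  const int OX = out_dim(X, ksize, pad, stride);
  const int OY = out_dim(Y, ksize, pad, stride);
  const int OZ = out_dim(Z, ksize, pad, stride);
  if (OX < 1 || OY < 1 || OZ < 1)
    stop("input spatial shape too small for this convolution");
  const int Cout = weight.nrow();
  if (weight.ncol() != C * ksize * ksize * ksize)
    stop("weight shape does not match input channels/kernel");

  arma::mat cols(C * ksize * ksize * ksize, OX * OY * OZ);
  im2col(REAL(input), C, X, Y, Z, ksize, pad, stride, OX, OY, OZ, cols);
  arma::mat W(weight.begin(), Cout, weight.ncol(), false);
  arma::mat out = W * cols;
  out.each_col() += arma::vec(bias.begin(), Cout);

  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Cout, OX, OY, OZ);
  return res;
}

// [[Rcpp::export(name = ".conv3dBackward")]]
List conv3dBackward(NumericVector input, NumericMatrix weight,
                    NumericVector gradOut, int stride, int ksize) {
  IntegerVector dm = input.attr("dim");
  const int C = dm[0], X = dm[1], Y = dm[2], Z = dm[3];
  const int pad = (ksize - 1) / 2;
  const int OX = out_dim(X, ksize, pad, stride);
  const int OY = out_dim(Y, ksize, pad, stride);
  const int OZ = out_dim(Z, ksize, pad, stride);
  const int Cout = weight.nrow();
  const int Nout = OX * OY * OZ;

  arma::mat cols(C * ksize * ksize * ksize, Nout);
  im2col(REAL(input), C, X, Y, Z, ksize, pad, stride, OX, OY, OZ, cols);

  arma::mat W(weight.begin(), Cout, weight.ncol(), false);
  arma::mat G(REAL(gradOut), Cout, Nout, false);

  arma::mat gradW = G * cols.t();
  arma::vec gradB = arma::sum(G, 1);
  arma::mat gradCols = W.t() * G;

  NumericVector gradInput((size_t)C * X * Y * Z);
  col2im(gradCols, C, X, Y, Z, ksize, pad, stride, OX, OY, OZ,
         REAL(gradInput));
  gradInput.attr("dim") = IntegerVector::create(C, X, Y, Z);

  return List::create(_["gradInput"] = gradInput,
                      _["gradWeight"] = NumericMatrix(Cout, weight.ncol(),
                                                      gradW.begin()),
                      _["gradBias"] = NumericVector(gradB.begin(),
                                                    gradB.end()));
}
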