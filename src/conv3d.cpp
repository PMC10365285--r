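// 3D convolution primitives for the patch-based SR networks.
//
// Layout conventions (column-major, as R stores arrays):
//   x : [D1, D2, D3, Cin, N]      input batch (N cubes, Cin channels)
//   W : [k, k, k, Cin, Cout]      kernel (k odd); "same" output size
//   y : [D1, D2, D3, Cout, N]
// Boundary handling is mirror (reflect-without-edge-repeat) padding, so a
// dimension must be > k/2.  Implemented as im2col + one GEMM per batch
// element; the backward pass folds gradients of reflected voxels back into
// the interior so that d(loss)/d(x) is exact for the mirrored convolution.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reflect index i (may be out of range) into [0, n-1], mirror about the
// edge voxel: -1 -> 1, n -> n-2.  Assumes |overhang| < n.
static inline int reflect_idx(int i, int n) {
  if (i < 0) return -i;
  if (i >= n) return 2 * n - 2 - i;
  return i;
}

// Build im2col matrix A: rows = D1*D2*D3 voxels, cols = k*k*k*Cin,
// for one batch element (pointer xv into [D1,D2,D3,Cin]).
static void im2col_reflect(const double* xv, int D1, int D2, int D3, int Cin,
                           int k, arma::mat& A) {
  const int r = k / 2;
  const long nvox = (long)D1 * D2 * D3;
  long col = 0;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = xv + (long)c * nvox;
    for (int dz = 0; dz < k; ++dz) {
      for (int dy = 0; dy < k; ++dy) {
        for (int dx = 0; dx < k; ++dx) {
          double* acol = A.colptr(col++);
          long row = 0;
          for (int z = 0; z < D3; ++z) {
            const int zz = reflect_idx(z + dz - r, D3);
            for (int y = 0; y < D2; ++y) {
              const int yy = reflect_idx(y + dy - r, D2);
              const long base = ((long)zz * D2 + yy) * D1;
              for (int x = 0; x < D1; ++x) {
                const int xx = reflect_idx(x + dx - r, D1);
                acol[row++] = xc[base + xx];
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericVector W,
                                 NumericVector b, IntegerVector xdim) {
  const int D1 = xdim[0], D2 = xdim[1], D3 = xdim[2],
            Cin = xdim[3], N = xdim[4];
  IntegerVector wd = W.attr("dim");
  const int k = wd[0], Cout = wd[4];
  if (wd[3] != Cin) stop("kernel input channels do not match input");
  const long nvox = (long)D1 * D2 * D3;
  const int ncol = k * k * k * Cin;

  arma::mat Wm(const_cast<double*>(W.begin()), ncol, Cout, false, true);
  NumericVector y((R_xlen_t)nvox * Cout * N);
  arma::mat A(nvox, ncol);

  for (int n = 0; n < N; ++n) {
    const double* xv = x.begin() + (long)n * nvox * Cin;
    im2col_reflect(xv, D1, D2, D3, Cin, k, A);
    arma::mat Y(y.begin() + (long)n * nvox * Cout, nvox, Cout, false, true);
    Y = A * Wm;
    for (int c = 0; c < Cout; ++c) Y.col(c) += b[c];
  }
  y.attr("dim") = IntegerVector::create(D1, D2, D3, Cout, N);
  return y;
}

// Backward pass: given upstream gradient gy (same shape as the forward
// output), return gradients w.r.t. x, W and b.
// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(NumericVector x, NumericVector W, NumericVector gy,
                         IntegerVector xdim) {
  const int D1 = xdim[0], D2 = xdim[1], D3 = xdim[2],
            Cin = xdim[3], N = xdim[4];
  IntegerVector wd = W.attr("dim");
  const int k = wd[0], Cout = wd[4], r = k / 2;
  const long nvox = (long)D1 * D2 * D3;
  const int ncol = k * k * k * Cin;

  arma::mat Wm(const_cast<double*>(W.begin()), ncol, Cout, false, true);
  NumericVector gx((R_xlen_t)nvox * Cin * N);
  NumericVector gW((R_xlen_t)ncol * Cout);
  NumericVector gb(Cout);
  arma::mat gWm(gW.begin(), ncol, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat A(nvox, ncol), Gcols(nvox, ncol);

  for (int n = 0; n < N; ++n) {
    const double* xv = x.begin() + (long)n * nvox * Cin;
    im2col_reflect(xv, D1, D2, D3, Cin, k, A);
    arma::mat Gy(const_cast<double*>(gy.begin()) + (long)n * nvox * Cout,
                 nvox, Cout, false, true);
    gWm += A.t() * Gy;
    gbv += arma::sum(Gy, 0).t();
    // grad wrt im2col entries, scattered back (col2im with reflection)
    Gcols = Gy * Wm.t();
    double* gxv = gx.begin() + (long)n * nvox * Cin;
    long col = 0;
    for (int c = 0; c < Cin; ++c) {
      double* gxc = gxv + (long)c * nvox;
      for (int dz = 0; dz < k; ++dz) {
        for (int dy = 0; dy < k; ++dy) {
          for (int dx = 0; dx < k; ++dx) {
            const double* gcol = Gcols.colptr(col++);
            long row = 0;
            for (int z = 0; z < D3; ++z) {
              const int zz = reflect_idx(z + dz - r, D3);
              for (int y = 0; y < D2; ++y) {
                const int yy = reflect_idx(y + dy - r, D2);
                const long base = ((long)zz * D2 + yy) * D1;
                for (int x2 = 0; x2 < D1; ++x2) {
                  const int xx = reflect_idx(x2 + dx - r, D1);
                  gxc[base + xx] += gcol[row++];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(D1, D2, D3, Cin, N);
  gW.attr("dim") = wd;
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Block (boxcar) average down-sampling: each output voxel is the mean of a
// factor^3 block; trailing voxels that do not fill a block are dropped.
// [[Rcpp::export(name = ".block_average3")]]
NumericVector block_average3_cpp(NumericVector x, IntegerVector xdim, int f) {
  const int D1 = xdim[0], D2 = xdim[1], D3 = xdim[2];
  const int O1 = D1 / f, O2 = D2 / f, O3 = D3 / f;
  NumericVector y((R_xlen_t)O1 * O2 * O3);
  const double inv = 1.0 / ((double)f * f * f);
  for (int oz = 0; oz < O3; ++oz)
    for (int oy = 0; oy < O2; ++oy)
      for (int ox = 0; ox < O1; ++ox) {
        double s = 0.0;
        for (int dz = 0; dz < f; ++dz)
          for (int dy = 0; dy < f; ++dy) {
            const long base = ((long)(oz * f + dz) * D2 + (oy * f + dy)) * D1
                              + (long)ox * f;
            for (int dx = 0; dx < f; ++dx) s += x[base + dx];
          }
        y[((long)oz * O2 + oy) * O1 + ox] = s * inv;
      }
  y.attr("dim") = IntegerVector::create(O1, O2, O3);
  return y;
}
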