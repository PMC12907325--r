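// Convolution kernels for the segmentation network.
// Tensors are R arrays in (H, W, C, N) column-major layout; weights are
// (3, 3, Cin, Cout) for standard 3x3 convs, (3, 3, C) for depthwise convs
// and (Cin, Cout) for pointwise convs.  Shape-preserving padding
// (pad = dilation) throughout; all loops are single-threaded and
// deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::cube cubeView(double* p, int H, int W, int C) {
  return arma::cube(p, H, W, C, false, true);
}

static void dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  H = d[0]; W = d[1]; C = d[2]; N = (d.size() > 3) ? d[3] : 1;
}

// Accumulate  Y(out rows/cols) += w * X(shifted rows/cols)  for one tap.
static inline void tapAdd(arma::mat& Y, const arma::mat& X, double w,
                          int dy, int dx) {
  if (w == 0.0) return;
  const int H = Y.n_rows, W = Y.n_cols;
  int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
  int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
  if (r0 > r1 || c0 > c1) return;
  Y.submat(r0, c0, r1, c1) += w * X.submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx);
}

static inline double tapDot(const arma::mat& A, const arma::mat& B,
                            int dy, int dx) {
  const int H = A.n_rows, W = A.n_cols;
  int r0 = std::max(0, -dy), r1 = std::min(H - 1, H - 1 - dy);
  int c0 = std::max(0, -dx), c1 = std::min(W - 1, W - 1 - dx);
  if (r0 > r1 || c0 > c1) return 0.0;
  return arma::accu(B.submat(r0, c0, r1, c1) %
                    A.submat(r0 + dy, c0 + dx, r1 + dy, c1 + dx));
}

// [[Rcpp::export(name = ".conv3x3_fw")]]
NumericVector conv3x3_fw(NumericVector x, NumericVector w, int dilation,
                         bool depthwise) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int Cout = depthwise ? C : wd[3];
  NumericVector y(double(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* xp = REAL(x); double* yp = REAL(y); double* wp = REAL(w);
  const long sx = (long)H * W * C, sy = (long)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    arma::cube X = cubeView(xp + n * sx, H, W, C);
    arma::cube Y = cubeView(yp + n * sy, H, W, Cout);
    if (depthwise) {
      for (int c = 0; c < C; ++c) {
        arma::mat Ys(Y.slice_memptr(c), H, W, false, true);
        const arma::mat Xs(X.slice_memptr(c), H, W, false, true);
        for (int kj = 0; kj < 3; ++kj)
          for (int ki = 0; ki < 3; ++ki)
            tapAdd(Ys, Xs, wp[ki + 3 * kj + 9 * c],
                   (ki - 1) * dilation, (kj - 1) * dilation);
      }
    } else {
      for (int co = 0; co < Cout; ++co) {
        arma::mat Ys(Y.slice_memptr(co), H, W, false, true);
        for (int ci = 0; ci < C; ++ci) {
          const arma::mat Xs(X.slice_memptr(ci), H, W, false, true);
          const double* wb = wp + 9 * ci + 9 * (long)C * co;
          for (int kj = 0; kj < 3; ++kj)
            for (int ki = 0; ki < 3; ++ki)
              tapAdd(Ys, Xs, wb[ki + 3 * kj],
                     (ki - 1) * dilation, (kj - 1) * dilation);
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv3x3_bw")]]
List conv3x3_bw(NumericVector x, NumericVector w, NumericVector gy,
                int dilation, bool depthwise) {
  int H, W, C, N; dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int Cout = depthwise ? C : wd[3];
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericVector gw(w.size()); gw.attr("dim") = w.attr("dim");
  double* xp = REAL(x); double* wp = REAL(w); double* gyp = REAL(gy);
  double* gxp = REAL(gx); double* gwp = REAL(gw);
  const long sx = (long)H * W * C, sy = (long)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    arma::cube X = cubeView(xp + n * sx, H, W, C);
    arma::cube GX = cubeView(gxp + n * sx, H, W, C);
    arma::cube GY = cubeView(gyp + n * sy, H, W, Cout);
    if (depthwise) {
      for (int c = 0; c < C; ++c) {
        const arma::mat Xs(X.slice_memptr(c), H, W, false, true);
        arma::mat GXs(GX.slice_memptr(c), H, W, false, true);
        const arma::mat GYs(GY.slice_memptr(c), H, W, false, true);
        for (int kj = 0; kj < 3; ++kj)
          for (int ki = 0; ki < 3; ++ki) {
            int dy = (ki - 1) * dilation, dx = (kj - 1) * dilation;
            // gx: transpose of the tap (shift in the opposite direction)
            tapAdd(GXs, GYs, wp[ki + 3 * kj + 9 * c], -dy, -dx);
            gwp[ki + 3 * kj + 9 * c] += tapDot(Xs, GYs, dy, dx);
          }
      }
    } else {
      for (int co = 0; co < Cout; ++co) {
        const arma::mat GYs(GY.slice_memptr(co), H, W, false, true);
        for (int ci = 0; ci < C; ++ci) {
          const arma::mat Xs(X.slice_memptr(ci), H, W, false, true);
          arma::mat GXs(GX.slice_memptr(ci), H, W, false, true);
          double* wb = wp + 9 * ci + 9 * (long)C * co;
          double* gwb = gwp + 9 * ci + 9 * (long)C * co;
          for (int kj = 0; kj < 3; ++kj)
            for (int ki = 0; ki < 3; ++ki) {
              int dy = (ki - 1) * dilation, dx = (kj - 1) * dilation;
              tapAdd(GXs, GYs, wb[ki + 3 * kj], -dy, -dx);
              gwb[ki + 3 * kj] += tapDot(Xs, GYs, dy, dx);
            }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// [[Rcpp::export(name = ".conv1x1_fw")]]
NumericVector conv1x1_fw(NumericVector x, NumericMatrix w,
                         Nullable<NumericVector> bias) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Cout = w.ncol();
  NumericVector y(double(H) * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(w.begin(), C, Cout, false, true);
  const long sx = (long)H * W * C, sy = (long)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat X(REAL(x) + n * sx, (long)H * W, C, false, true);
    arma::mat Y(REAL(y) + n * sy, (long)H * W, Cout, false, true);
    Y = X * Wm;
    if (bias.isNotNull()) {
      NumericVector b(bias);
      for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv1x1_bw")]]
List conv1x1_bw(NumericVector x, NumericMatrix w, NumericVector gy,
                bool hasBias) {
  int H, W, C, N; dims4(x, H, W, C, N);
  int Cout = w.ncol();
  NumericVector gx(x.size()); gx.attr("dim") = x.attr("dim");
  NumericMatrix gw(C, Cout);
  NumericVector gb(Cout);
  arma::mat Wm(w.begin(), C, Cout, false, true);
  arma::mat GWm(gw.begin(), C, Cout, false, true);
  arma::vec GB(gb.begin(), Cout, false, true);
  const long sx = (long)H * W * C, sy = (long)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    arma::mat X(REAL(x) + n * sx, (long)H * W, C, false, true);
    arma::mat GX(REAL(gx) + n * sx, (long)H * W, C, false, true);
    arma::mat GY(REAL(gy) + n * sy, (long)H * W, Cout, false, true);
    GX = GY * Wm.t();
    GWm += X.t() * GY;
    if (hasBias) GB += arma::sum(GY, 0).t();
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
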