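// Batched 2D convolution via im2col + GEMM.  Arrays are R column-major:
// inputs (H, W, C, N), kernels (kh, kw, Cin, Cout), outputs (oh, ow, Cout, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dim4(const NumericVector& a, int d[4], const char* what) {
  SEXP ds = a.attr("dim");
  if (Rf_isNull(ds)) stop("%s must be a 4-d array", what);
  IntegerVector dim(ds);
  if (dim.size() != 4) stop("%s must be a 4-d array", what);
  for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

// Column p = oy + oh*ox of M holds the receptive field of output pixel (oy, ox).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int stride, int pad,
                   int oh, int ow, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride - pad + kj;
          if (ix < 0 || ix >= W) {
            for (int oy = 0; oy < oh; ++oy) M(r, oy + (std::size_t)oh * ox) = 0.0;
          } else {
            const double* col = xc + (std::size_t)H * ix;
            for (int oy = 0; oy < oh; ++oy) {
              const int iy = oy * stride - pad + ki;
              M(r, oy + (std::size_t)oh * ox) =
                (iy >= 0 && iy < H) ? col[iy] : 0.0;
            }
          }
        }
      }
    }
  }
}

static arma::mat kernel_matrix(const NumericVector& w,
                               int kh, int kw, int Cin, int Cout) {
  arma::mat Wm(Cout, (std::size_t)kh * kw * Cin);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wm(co, ki + kh * (kj + kw * c)) =
            w[ki + (std::size_t)kh * (kj + (std::size_t)kw * (c + (std::size_t)Cin * co))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  int xd[4], wd[4];
  get_dim4(x, xd, "x");
  get_dim4(w, wd, "w");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C)
    stop("channel mismatch: input has %d channels but kernel expects %d", C, Cin);
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than padded input");
  const int K = kh * kw * C, P = oh * ow;
  arma::mat Wm = kernel_matrix(w, kh, kw, Cin, Cout);
  NumericVector out((std::size_t)P * Cout * N);
  arma::mat M(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(REAL(x) + (std::size_t)n * H * W * C, H, W, C,
           kh, kw, stride, pad, oh, ow, M);
    arma::mat O = Wm * M;
    double* op = REAL(out) + (std::size_t)n * P * Cout;
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      for (int p = 0; p < P; ++p) op[p + (std::size_t)P * co] = O(co, p) + bc;
    }
  }
  out.attr("dim") = IntegerVector::create(oh, ow, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  int xd[4], wd[4], gd[4];
  get_dim4(x, xd, "x");
  get_dim4(w, wd, "w");
  get_dim4(gy, gd, "gy");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  const int oh = gd[0], ow = gd[1];
  const int K = kh * kw * C, P = oh * ow;
  arma::mat Wm = kernel_matrix(w, kh, kw, Cin, Cout);
  arma::mat Gw(Cout, K, arma::fill::zeros);
  NumericVector gx((std::size_t)H * W * C * N);
  NumericVector gb(Cout);
  arma::mat M(K, P), Gyn(Cout, P);
  for (int n = 0; n < N; ++n) {
    const double* gp = REAL(gy) + (std::size_t)n * P * Cout;
    for (int co = 0; co < Cout; ++co) {
      double s = 0.0;
      for (int p = 0; p < P; ++p) {
        Gyn(co, p) = gp[p + (std::size_t)P * co];
        s += Gyn(co, p);
      }
      gb[co] += s;
    }
    im2col(REAL(x) + (std::size_t)n * H * W * C, H, W, C,
           kh, kw, stride, pad, oh, ow, M);
    Gw += Gyn * M.t();
    arma::mat Col = Wm.t() * Gyn;  // K x P
    double* gxn = REAL(gx) + (std::size_t)n * H * W * C;
    for (int c = 0; c < C; ++c) {
      double* gxc = gxn + (std::size_t)c * H * W;
      for (int kj = 0; kj < kw; ++kj) {
        for (int ki = 0; ki < kh; ++ki) {
          const int r = ki + kh * (kj + kw * c);
          for (int ox = 0; ox < ow; ++ox) {
            const int ix = ox * stride - pad + kj;
            if (ix < 0 || ix >= W) continue;
            double* col = gxc + (std::size_t)H * ix;
            for (int oy = 0; oy < oh; ++oy) {
              const int iy = oy * stride - pad + ki;
              if (iy >= 0 && iy < H) col[iy] += Col(r, oy + (std::size_t)oh * ox);
            }
          }
        }
      }
    }
  }
  NumericVector gw((std::size_t)kh * kw * Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          gw[ki + (std::size_t)kh * (kj + (std::size_t)kw * (c + (std::size_t)Cin * co))] =
            Gw(co, ki + kh * (kj + kw * c));
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
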