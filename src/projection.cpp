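// Ray reduction of a 3D volume along transverse axis 1 or 2.
// op: 0 = max, 1 = mean over the full ray, 2 = mean over voxels != fill.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_reduce_axis(NumericVector v, int axis, int op, double fill) {
  SEXP ds = v.attr("dim");
  if (Rf_isNull(ds)) stop("volume must be a 3-d array");
  IntegerVector dim(ds);
  if (dim.size() != 3) stop("volume must be a 3-d array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* x = REAL(v);
  const int nt = (axis == 1) ? ny : nx;   // transverse output size
  NumericMatrix out(nt, nz);
  std::vector<double> cnt;
  if (op == 2) cnt.assign((std::size_t)nt, 0.0);
  for (int z = 0; z < nz; ++z) {
    double* o = &out(0, z);
    if (op == 0) {
      for (int t = 0; t < nt; ++t) o[t] = R_NegInf;
    } else {
      for (int t = 0; t < nt; ++t) o[t] = 0.0;
      if (op == 2) std::fill(cnt.begin(), cnt.end(), 0.0);
    }
    const double* slice = x + (std::size_t)z * nx * ny;
    for (int y = 0; y < ny; ++y) {
      const double* col = slice + (std::size_t)y * nx;
      if (axis == 1) {            // reduce over x; output indexed by y
        if (op == 0) {
          double m = R_NegInf;
          for (int i = 0; i < nx; ++i) if (col[i] > m) m = col[i];
          o[y] = m;
        } else if (op == 1) {
          double s = 0.0;
          for (int i = 0; i < nx; ++i) s += col[i];
          o[y] = s / nx;
        } else {
          double s = 0.0; double c = 0.0;
          for (int i = 0; i < nx; ++i) if (col[i] != fill) { s += col[i]; ++c; }
          o[y] = (c > 0) ? s / c : fill;
        }
      } else {                    // reduce over y; output indexed by x
        if (op == 0) {
          for (int i = 0; i < nx; ++i) if (col[i] > o[i]) o[i] = col[i];
        } else if (op == 1) {
          for (int i = 0; i < nx; ++i) o[i] += col[i];
        } else {
          for (int i = 0; i < nx; ++i)
            if (col[i] != fill) { o[i] += col[i]; cnt[i] += 1.0; }
        }
      }
    }
    if (axis == 2) {
      if (op == 1) {
        for (int i = 0; i < nx; ++i) o[i] /= ny;
      } else if (op == 2) {
        for (int i = 0; i < nx; ++i) o[i] = (cnt[i] > 0) ? o[i] / cnt[i] : fill;
      }
    }
  }
  return out;
}
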