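// Convolution kernels (im2col + GEMM) for the 2D encoder and 3D
// decoder/discriminator. Tensors arrive as flat R arrays in column-major
// layout: 2D features are (n1, n2, C), 3D features are (n1, n2, n3, C).
// Weights are (Cin * k^nd) x Cout matrices; the row order is
// channel-major, then kernel offsets with axis 1 fastest. "Same" padding
// (k/2) with zeros; output spatial extent is (n + 2*pad - k)/stride + 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int n, int k, int stride) {
  int pad = k / 2;
  return (n + 2 * pad - k) / stride + 1;
}

// ---------------------------------------------------------------- 2D ----

static arma::mat im2col2(const double* x, int n1, int n2, int cin,
                         int k, int stride) {
  const int pad = k / 2;
  const int o1 = out_extent(n1, k, stride);
  const int o2 = out_extent(n2, k, stride);
  arma::mat colsT(static_cast<arma::uword>(o1) * o2,
                  static_cast<arma::uword>(cin) * k * k,
                  arma::fill::zeros);
  arma::uword col = 0;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + static_cast<size_t>(n1) * n2 * c;
    for (int k2 = 0; k2 < k; ++k2) {
      for (int k1 = 0; k1 < k; ++k1, ++col) {
        double* dst = colsT.colptr(col);
        for (int p2 = 0; p2 < o2; ++p2) {
          const int i2 = p2 * stride + k2 - pad;
          if (i2 < 0 || i2 >= n2) continue;
          const double* xs = xc + static_cast<size_t>(n1) * i2;
          double* d2 = dst + static_cast<size_t>(p2) * o1;
          for (int p1 = 0; p1 < o1; ++p1) {
            const int i1 = p1 * stride + k1 - pad;
            if (i1 >= 0 && i1 < n1) d2[p1] = xs[i1];
          }
        }
      }
    }
  }
  return colsT;
}

static void col2im2(const arma::mat& colsT, double* gx, int n1, int n2,
                    int cin, int k, int stride) {
  const int pad = k / 2;
  const int o1 = out_extent(n1, k, stride);
  const int o2 = out_extent(n2, k, stride);
  arma::uword col = 0;
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + static_cast<size_t>(n1) * n2 * c;
    for (int k2 = 0; k2 < k; ++k2) {
      for (int k1 = 0; k1 < k; ++k1, ++col) {
        const double* src = colsT.colptr(col);
        for (int p2 = 0; p2 < o2; ++p2) {
          const int i2 = p2 * stride + k2 - pad;
          if (i2 < 0 || i2 >= n2) continue;
          double* gs = gc + static_cast<size_t>(n1) * i2;
          const double* s2 = src + static_cast<size_t>(p2) * o1;
          for (int p1 = 0; p1 < o1; ++p1) {
            const int i1 = p1 * stride + k1 - pad;
            if (i1 >= 0 && i1 < n1) gs[i1] += s2[p1];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2_fw(NumericVector x, IntegerVector dims,
                       NumericMatrix w, NumericVector b,
                       int k, int stride) {
  const int n1 = dims[0], n2 = dims[1], cin = dims[2];
  const int cout = w.ncol();
  arma::mat colsT = im2col2(x.begin(), n1, n2, cin, k, stride);
  const arma::mat wA(const_cast<double*>(w.begin()), w.nrow(), w.ncol(),
                     false, true);
  arma::mat y = colsT * wA;  // (npos x cout)
  for (int c = 0; c < cout; ++c) y.col(c) += b[c];
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(out_extent(n1, k, stride),
                                          out_extent(n2, k, stride), cout);
  return out;
}

// [[Rcpp::export]]
List conv2_bw(NumericVector x, IntegerVector dims,
              NumericMatrix w, NumericVector gy,
              int k, int stride, bool need_gx) {
  const int n1 = dims[0], n2 = dims[1], cin = dims[2];
  const int cout = w.ncol();
  const arma::uword npos = static_cast<arma::uword>(out_extent(n1, k, stride)) *
                           out_extent(n2, k, stride);
  arma::mat colsT = im2col2(x.begin(), n1, n2, cin, k, stride);
  const arma::mat gyA(const_cast<double*>(gy.begin()), npos, cout, false, true);
  arma::mat gw = colsT.t() * gyA;
  arma::rowvec gb = arma::sum(gyA, 0);
  NumericVector gxv;
  if (need_gx) {
    const arma::mat wA(const_cast<double*>(w.begin()), w.nrow(), w.ncol(),
                       false, true);
    arma::mat gcolsT = gyA * wA.t();
    gxv = NumericVector(x.size());
    col2im2(gcolsT, gxv.begin(), n1, n2, cin, k, stride);
    gxv.attr("dim") = dims;
  }
  return List::create(_["gw"] = wrap(gw), _["gb"] = NumericVector(gb.begin(), gb.end()),
                      _["gx"] = gxv);
}

// ---------------------------------------------------------------- 3D ----

static arma::mat im2col3(const double* x, int n1, int n2, int n3, int cin,
                         int k, int stride) {
  const int pad = k / 2;
  const int o1 = out_extent(n1, k, stride);
  const int o2 = out_extent(n2, k, stride);
  const int o3 = out_extent(n3, k, stride);
  arma::mat colsT(static_cast<arma::uword>(o1) * o2 * o3,
                  static_cast<arma::uword>(cin) * k * k * k,
                  arma::fill::zeros);
  arma::uword col = 0;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + static_cast<size_t>(n1) * n2 * n3 * c;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1, ++col) {
          double* dst = colsT.colptr(col);
          for (int p3 = 0; p3 < o3; ++p3) {
            const int i3 = p3 * stride + k3 - pad;
            if (i3 < 0 || i3 >= n3) continue;
            const double* x3 = xc + static_cast<size_t>(n1) * n2 * i3;
            double* d3 = dst + static_cast<size_t>(p3) * o1 * o2;
            for (int p2 = 0; p2 < o2; ++p2) {
              const int i2 = p2 * stride + k2 - pad;
              if (i2 < 0 || i2 >= n2) continue;
              const double* xs = x3 + static_cast<size_t>(n1) * i2;
              double* d2 = d3 + static_cast<size_t>(p2) * o1;
              for (int p1 = 0; p1 < o1; ++p1) {
                const int i1 = p1 * stride + k1 - pad;
                if (i1 >= 0 && i1 < n1) d2[p1] = xs[i1];
              }
            }
          }
        }
  }
  return colsT;
}

static void col2im3(const arma::mat& colsT, double* gx, int n1, int n2,
                    int n3, int cin, int k, int stride) {
  const int pad = k / 2;
  const int o1 = out_extent(n1, k, stride);
  const int o2 = out_extent(n2, k, stride);
  const int o3 = out_extent(n3, k, stride);
  arma::uword col = 0;
  for (int c = 0; c < cin; ++c) {
    double* gc = gx + static_cast<size_t>(n1) * n2 * n3 * c;
    for (int k3 = 0; k3 < k; ++k3)
      for (int k2 = 0; k2 < k; ++k2)
        for (int k1 = 0; k1 < k; ++k1, ++col) {
          const double* src = colsT.colptr(col);
          for (int p3 = 0; p3 < o3; ++p3) {
            const int i3 = p3 * stride + k3 - pad;
            if (i3 < 0 || i3 >= n3) continue;
            double* g3 = gc + static_cast<size_t>(n1) * n2 * i3;
            const double* s3 = src + static_cast<size_t>(p3) * o1 * o2;
            for (int p2 = 0; p2 < o2; ++p2) {
              const int i2 = p2 * stride + k2 - pad;
              if (i2 < 0 || i2 >= n2) continue;
              double* gs = g3 + static_cast<size_t>(n1) * i2;
              const double* s2 = s3 + static_cast<size_t>(p2) * o1;
              for (int p1 = 0; p1 < o1; ++p1) {
                const int i1 = p1 * stride + k1 - pad;
                if (i1 >= 0 && i1 < n1) gs[i1] += s2[p1];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector conv3_fw(NumericVector x, IntegerVector dims,
                       NumericMatrix w, NumericVector b,
                       int k, int stride) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2], cin = dims[3];
  const int cout = w.ncol();
  arma::mat colsT = im2col3(x.begin(), n1, n2, n3, cin, k, stride);
  const arma::mat wA(const_cast<double*>(w.begin()), w.nrow(), w.ncol(),
                     false, true);
  arma::mat y = colsT * wA;
  for (int c = 0; c < cout; ++c) y.col(c) += b[c];
  NumericVector out(y.begin(), y.end());
  out.attr("dim") = IntegerVector::create(out_extent(n1, k, stride),
                                          out_extent(n2, k, stride),
                                          out_extent(n3, k, stride), cout);
  return out;
}

// [[Rcpp::export]]
List conv3_bw(NumericVector x, IntegerVector dims,
              NumericMatrix w, NumericVector gy,
              int k, int stride, bool need_gx) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2], cin = dims[3];
  const int cout = w.ncol();
  const arma::uword npos = static_cast<arma::uword>(out_extent(n1, k, stride)) *
                           out_extent(n2, k, stride) * out_extent(n3, k, stride);
  arma::mat colsT = im2col3(x.begin(), n1, n2, n3, cin, k, stride);
  const arma::mat gyA(const_cast<double*>(gy.begin()), npos, cout, false, true);
  arma::mat gw = colsT.t() * gyA;
  arma::rowvec gb = arma::sum(gyA, 0);
  NumericVector gxv;
  if (need_gx) {
    const arma::mat wA(const_cast<double*>(w.begin()), w.nrow(), w.ncol(),
                       false, true);
    arma::mat gcolsT = gyA * wA.t();
    gxv = NumericVector(x.size());
    col2im3(gcolsT, gxv.begin(), n1, n2, n3, cin, k, stride);
    gxv.attr("dim") = dims;
  }
  return List::create(_["gw"] = wrap(gw), _["gb"] = NumericVector(gb.begin(), gb.end()),
                      _["gx"] = gxv);
}
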