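// Low-level numeric kernels: 2D convolution (im2col + GEMM), 2x2 max pooling,
// nearest-neighbour upsampling, and an exact anisotropic squared Euclidean
// distance transform. Array layout throughout: column-major (H, W, C, B) for
// image batches and (k, k, Cin, Cout) for convolution weights, so a weight
// array is addressable as a (k*k*Cin) x Cout matrix without copying.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;


static NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}
static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector dims_of(const NumericVector& x) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("input must be a dimensioned array");
  return IntegerVector(d);
}

// Fill the transposed im2col matrix (H*W x k*k*Cin) for one image with zero
// padding, stride 1, odd kernel size. The transposed layout keeps both the
// writes here and the reads in col2im_add contiguous.
static void im2col_t(const double* x, int H, int W, int Cin, int k,
                     arma::mat& colT) {
  const int p = (k - 1) / 2;
  const size_t N = (size_t)H * W;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int row = a + k * (b + k * c);
        double* dst = colT.memptr() + N * row;
        for (int w = 0; w < W; ++w) {
          const int sw = w + b - p;
          double* dcol = dst + (size_t)H * w;
          if (sw < 0 || sw >= W) {
            std::fill(dcol, dcol + H, 0.0);
          } else {
            const double* src = xc + (size_t)sw * H + (a - p);
            const int h0 = std::max(0, p - a), h1 = H - std::max(0, a - p);
            for (int h = 0; h < h0; ++h) dcol[h] = 0.0;
            for (int h = h1; h < H; ++h) dcol[h] = 0.0;
            std::copy(src + h0, src + h1, dcol + h0);
          }
        }
      }
    }
  }
}

// Scatter-add of a (transposed) column matrix back to image layout
// (adjoint of im2col_t).
static void col2im_add(const arma::mat& colT, int H, int W, int Cin, int k,
                       double* dx) {
  const int p = (k - 1) / 2;
  const size_t N = (size_t)H * W;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dx + (size_t)c * H * W;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int row = a + k * (b + k * c);
        const double* src = colT.memptr() + N * row;
        for (int w = 0; w < W; ++w) {
          const int sw = w + b - p;
          if (sw < 0 || sw >= W) continue;
          double* dstc = xc + (size_t)sw * H + (a - p);
          const double* scol = src + (size_t)H * w;
          const int h0 = std::max(0, p - a), h1 = H - std::max(0, a - p);
          for (int h = h0; h < h1; ++h) dstc[h] += scol[h];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  if (xd.size() != 4 || wd.size() != 4) stop("x must be (H,W,C,B), w (k,k,Cin,Cout)");
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != Cin) stop("weight dims inconsistent with input");
  if (bias.size() != Cout) stop("bias length must equal Cout");
  const int K = k * k * Cin, N = H * W;

  NumericVector out = alloc4d(H, W, Cout, B);
  const arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat colT(N, K);
  for (int img = 0; img < B; ++img) {
    im2col_t(x.begin() + (size_t)img * H * W * Cin, H, W, Cin, k, colT);
    arma::mat Y(out.begin() + (size_t)img * N * Cout, N, Cout, false, true);
    Y = colT * Wmat;
    for (int c = 0; c < Cout; ++c) Y.col(c) += bias[c];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = dims_of(x), wd = dims_of(w), yd = dims_of(dy);
  const int H = xd[0], W = xd[1], Cin = xd[2], B = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (yd[0] != H || yd[1] != W || yd[2] != Cout || yd[3] != B)
    stop("dy dims inconsistent");
  const int K = k * k * Cin, N = H * W;

  NumericVector dx = alloc4d(H, W, Cin, B);
  NumericVector dw = alloc4d(k, k, Cin, Cout);
  NumericVector db(Cout);
  const arma::mat Wmat(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWmat(dw.begin(), K, Cout, false, true);
  arma::vec dbv(db.begin(), Cout, false, true);
  arma::mat colT(N, K);
  for (int img = 0; img < B; ++img) {
    const arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)img * N * Cout,
                       N, Cout, false, true);
    im2col_t(x.begin() + (size_t)img * H * W * Cin, H, W, Cin, k, colT);
    dWmat += colT.t() * dY;
    dbv += arma::sum(dY, 0).t();
    arma::mat dcolT = dY * Wmat.t();
    col2im_add(dcolT, H, W, Cin, k, dx.begin() + (size_t)img * H * W * Cin);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 2 || W % 2) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4d(Ho, Wo, C, B);
  IntegerVector idx = alloc4i(Ho, Wo, C, B);   // 1-based flat index into x
  const double* px = x.begin();
  double* py = y.begin();
  int* pi = idx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const size_t xoff = (size_t)cb * H * W, yoff = (size_t)cb * Ho * Wo;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        size_t base = xoff + (size_t)(2 * w) * H + 2 * h;
        size_t best = base;
        double bv = px[base];
        const size_t cand[3] = { base + 1, base + H, base + H + 1 };
        for (int t = 0; t < 3; ++t)
          if (px[cand[t]] > bv) { bv = px[cand[t]]; best = cand[t]; }
        py[yoff + (size_t)w * Ho + h] = bv;
        pi[yoff + (size_t)w * Ho + h] = (int)(best + 1);
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy, IntegerVector xdim) {
  NumericVector dx = alloc4d(xdim[0], xdim[1], xdim[2], xdim[3]);
  const int n = dy.size();
  for (int i = 0; i < n; ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector xd = dims_of(x);
  const int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  NumericVector y = alloc4d(2 * H, 2 * W, C, B);
  const double* px = x.begin();
  double* py = y.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const size_t xoff = (size_t)cb * H * W, yoff = (size_t)cb * 4 * H * W;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double v = px[xoff + (size_t)w * H + h];
        size_t o = yoff + (size_t)(2 * w) * 2 * H + 2 * h;
        py[o] = v; py[o + 1] = v;
        py[o + 2 * H] = v; py[o + 2 * H + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dy) {
  IntegerVector yd = dims_of(dy);
  const int H2 = yd[0], W2 = yd[1], C = yd[2], B = yd[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx = alloc4d(H, W, C, B);
  const double* py = dy.begin();
  double* px = dx.begin();
  for (int cb = 0; cb < C * B; ++cb) {
    const size_t xoff = (size_t)cb * H * W, yoff = (size_t)cb * H2 * W2;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t o = yoff + (size_t)(2 * w) * H2 + 2 * h;
        px[xoff + (size_t)w * H + h] =
          py[o] + py[o + 1] + py[o + H2] + py[o + H2 + 1];
      }
  }
  return dx;
}

// ---- exact squared Euclidean distance transform (separable lower envelope) --

static const double EDT_INF = 1e30;

// 1D squared distance transform over samples at positions pos[i], values f[i].
static void dt1d(const double* f, const double* pos, int n,
                 double* d, int* v, double* z) {
  int kk = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  const auto intersect = [&](int q, int p) {
    return ((f[q] + pos[q] * pos[q]) - (f[p] + pos[p] * pos[p])) /
           (2.0 * pos[q] - 2.0 * pos[p]);
  };
  for (int q = 1; q < n; ++q) {
    double s = intersect(q, v[kk]);
    // the kk > 0 guard matters: with large finite sentinels for empty
    // samples the intersection can fall below z[0] = -inf-sentinel
    while (kk > 0 && s <= z[kk]) {
      --kk;
      s = intersect(q, v[kk]);
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = EDT_INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < pos[q]) ++kk;
    const double diff = pos[q] - pos[v[kk]];
    d[q] = diff * diff + f[v[kk]];
    if (d[q] > EDT_INF) d[q] = EDT_INF;
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest nonzero
// voxel centre of `mask`, honouring per-axis spacing. All-zero masks return
// a volume of +Inf-like sentinels (1e30).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(NumericVector mask, NumericVector spacing) {
  IntegerVector md = dims_of(mask);
  if (md.size() != 3) stop("mask must be 3D");
  const int n1 = md[0], n2 = md[1], n3 = md[2];
  NumericVector d(Dimension(n1, n2, n3));
  const size_t ntot = (size_t)n1 * n2 * n3;
  for (size_t i = 0; i < ntot; ++i) d[i] = mask[i] > 0 ? 0.0 : EDT_INF;

  const int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1), pos(nmax);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int i = 0; i < n1; ++i) pos[i] = i * spacing[0];
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k2 = 0; k2 < n2; ++k2) {
      double* line = d.begin() + (size_t)n1 * (k2 + (size_t)n2 * k3);
      std::copy(line, line + n1, f.begin());
      dt1d(f.data(), pos.data(), n1, dd.data(), v.data(), z.data());
      std::copy(dd.begin(), dd.begin() + n1, line);
    }
  // axis 2 (stride n1)
  for (int i = 0; i < n2; ++i) pos[i] = i * spacing[1];
  for (int k3 = 0; k3 < n3; ++k3)
    for (int k1 = 0; k1 < n1; ++k1) {
      double* base = d.begin() + k1 + (size_t)n1 * n2 * k3;
      for (int i = 0; i < n2; ++i) f[i] = base[(size_t)i * n1];
      dt1d(f.data(), pos.data(), n2, dd.data(), v.data(), z.data());
      for (int i = 0; i < n2; ++i) base[(size_t)i * n1] = dd[i];
    }
  // axis 3 (stride n1*n2)
  for (int i = 0; i < n3; ++i) pos[i] = i * spacing[2];
  const size_t s3 = (size_t)n1 * n2;
  for (int k2 = 0; k2 < n2; ++k2)
    for (int k1 = 0; k1 < n1; ++k1) {
      double* base = d.begin() + k1 + (size_t)n1 * k2;
      for (int i = 0; i < n3; ++i) f[i] = base[(size_t)i * s3];
      dt1d(f.data(), pos.data(), n3, dd.data(), v.data(), z.data());
      for (int i = 0; i < n3; ++i) base[(size_t)i * s3] = dd[i];
    }
  return d;
}
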