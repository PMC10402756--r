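// Numerical kernels for the network layers and the surface-distance
// transform.  Feature maps are R arrays with dim (H, W, C, N), column-major,
// so an (H, W) slice for one channel of one sample is contiguous.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static IntegerVector dims4(const NumericVector& x, const char* what) {
  SEXP d = x.attr("dim");
  if (Rf_isNull(d)) stop("%s must be a 4-d array", what);
  IntegerVector dd(d);
  if (dd.size() != 4) stop("%s must be a 4-d array", what);
  return dd;
}

// ---------------------------------------------------------------------------
// Dilated 2D convolution, "same" zero padding of (D-1)/2 per side where
// D = K + (K-1)(R-1).  Implemented as a sum over the K*K kernel offsets of
// a (H*W x Ci) x (Ci x Co) GEMM, which keeps peak memory at one feature map.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int dilation) {
  IntegerVector xd = dims4(x, "input"), wd = dims4(w, "kernel");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int K = wd[0], Co = wd[3];
  if (wd[1] != K) stop("kernel must be square");
  if (K < 1 || K % 2 == 0) stop("kernel size must be odd and positive");
  if (dilation < 1) stop("dilation rate must be >= 1");
  if (wd[2] != Ci)
    stop("channel mismatch: input has %d channels, kernel expects %d", Ci, wd[2]);
  if ((int)b.size() != Co) stop("bias length must equal out_channels");

  const int pad = (K - 1) * dilation / 2;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const size_t HW = (size_t)H * W;

  std::vector<arma::mat> Wk((size_t)K * K, arma::mat(Ci, Co));
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kj = 0; kj < K; ++kj)
        for (int ki = 0; ki < K; ++ki)
          Wk[ki + (size_t)K * kj](ci, co) =
              w[ki + (size_t)K * (kj + (size_t)K * (ci + (size_t)Ci * co))];

  NumericVector y(HW * Co * N);
  y.attr("dim") = IntegerVector::create(H, W, Co, N);

  arma::cube xpad(Hp, Wp, Ci);
  arma::mat Xs(HW, Ci), Y(HW, Co);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    xpad.zeros();
    for (int c = 0; c < Ci; ++c) {
      arma::mat xin(const_cast<double*>(xp + ((size_t)n * Ci + c) * HW),
                    H, W, false, true);
      xpad.slice(c).submat(pad, pad, pad + H - 1, pad + W - 1) = xin;
    }
    for (int co = 0; co < Co; ++co) Y.col(co).fill(b[co]);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int oi = ki * dilation, oj = kj * dilation;
        for (int c = 0; c < Ci; ++c)
          Xs.col(c) = arma::vectorise(
              xpad.slice(c).submat(oi, oj, oi + H - 1, oj + W - 1));
        Y += Xs * Wk[ki + (size_t)K * kj];
      }
    }
    std::copy(Y.memptr(), Y.memptr() + HW * Co, yp + (size_t)n * HW * Co);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int dilation) {
  IntegerVector xd = dims4(x, "input"), wd = dims4(w, "kernel");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int K = wd[0], Co = wd[3];
  const int pad = (K - 1) * dilation / 2;
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const size_t HW = (size_t)H * W;

  std::vector<arma::mat> Wk((size_t)K * K, arma::mat(Ci, Co));
  std::vector<arma::mat> dWk((size_t)K * K, arma::mat(Ci, Co, arma::fill::zeros));
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kj = 0; kj < K; ++kj)
        for (int ki = 0; ki < K; ++ki)
          Wk[ki + (size_t)K * kj](ci, co) =
              w[ki + (size_t)K * (kj + (size_t)K * (ci + (size_t)Ci * co))];

  NumericVector dx(HW * Ci * N);
  dx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  NumericVector db(Co);

  arma::cube xpad(Hp, Wp, Ci), dxpad(Hp, Wp, Ci);
  arma::mat Xs(HW, Ci), G(HW, Ci);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int n = 0; n < N; ++n) {
    xpad.zeros();
    dxpad.zeros();
    for (int c = 0; c < Ci; ++c) {
      arma::mat xin(const_cast<double*>(xp + ((size_t)n * Ci + c) * HW),
                    H, W, false, true);
      xpad.slice(c).submat(pad, pad, pad + H - 1, pad + W - 1) = xin;
    }
    arma::mat dY(const_cast<double*>(dyp + (size_t)n * HW * Co), HW, Co,
                 false, true);
    for (int co = 0; co < Co; ++co) db[co] += arma::accu(dY.col(co));
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const int oi = ki * dilation, oj = kj * dilation;
        for (int c = 0; c < Ci; ++c)
          Xs.col(c) = arma::vectorise(
              xpad.slice(c).submat(oi, oj, oi + H - 1, oj + W - 1));
        dWk[ki + (size_t)K * kj] += Xs.t() * dY;
        G = dY * Wk[ki + (size_t)K * kj].t();
        for (int c = 0; c < Ci; ++c)
          dxpad.slice(c).submat(oi, oj, oi + H - 1, oj + W - 1) +=
              arma::reshape(G.col(c), H, W);
      }
    }
    for (int c = 0; c < Ci; ++c) {
      arma::mat dxs = dxpad.slice(c).submat(pad, pad, pad + H - 1, pad + W - 1);
      std::copy(dxs.memptr(), dxs.memptr() + HW,
                dxp + ((size_t)n * Ci + c) * HW);
    }
  }

  NumericVector dw((size_t)K * K * Ci * Co);
  dw.attr("dim") = wd;
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int kj = 0; kj < K; ++kj)
        for (int ki = 0; ki < K; ++ki)
          dw[ki + (size_t)K * (kj + (size_t)K * (ci + (size_t)Ci * co))] =
              dWk[ki + (size_t)K * kj](ci, co);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// 2x2 max pooling (stride 2); argmax indices (0-based, into the full input
// vector) are kept for the backward scatter.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x, "input");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 != 0 || W % 2 != 0) stop("spatial dims must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx(y.size());
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* ip = REAL(idx);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t k00 = base + (size_t)(2 * j) * H + 2 * i;
          size_t best = k00;
          double v = xp[k00];
          const size_t cand[3] = {k00 + 1, k00 + (size_t)H, k00 + (size_t)H + 1};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > v) { v = xp[cand[t]]; best = cand[t]; }
          // note column-major: advance output by (i, j) explicitly
          size_t oo = ((size_t)n * C + c) * Ho * Wo + (size_t)j * Ho + i;
          yp[oo] = v;
          ip[oo] = (double)best;
          ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, NumericVector idx,
                               IntegerVector in_dim) {
  NumericVector dx((size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3]);
  dx.attr("dim") = in_dim;
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const double* ip = REAL(idx);
  const size_t n = dy.size();
  for (size_t t = 0; t < n; ++t) dxp[(size_t)ip[t]] += dyp[t];
  return dx;
}

// ---------------------------------------------------------------------------
// Block average pooling by an integer factor f (adaptive pooling onto the
// transformer token grid), and its adjoint.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_avgpool_fwd(NumericVector x, int f) {
  IntegerVector xd = dims4(x, "input");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (f < 1 || H % f != 0 || W % f != 0)
    stop("pooling factor must divide the spatial dims");
  const int Ho = H / f, Wo = W / f;
  const double inv = 1.0 / ((double)f * f);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const size_t obase = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          double s = 0.0;
          for (int dj = 0; dj < f; ++dj)
            for (int di = 0; di < f; ++di)
              s += xp[base + (size_t)(j * f + dj) * H + i * f + di];
          yp[obase + (size_t)j * Ho + i] = s * inv;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bwd(NumericVector dy, int f) {
  IntegerVector yd = dims4(dy, "gradient");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho * f, W = Wo * f;
  const double inv = 1.0 / ((double)f * f);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      const size_t obase = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double g = dyp[obase + (size_t)j * Ho + i] * inv;
          for (int dj = 0; dj < f; ++dj)
            for (int di = 0; di < f; ++di)
              dxp[base + (size_t)(j * f + dj) * H + i * f + di] += g;
        }
    }
  return dx;
}

// ---------------------------------------------------------------------------
// Bilinear resize (half-pixel centers, edge-clamped) and its adjoint.
// ---------------------------------------------------------------------------

static void resize_weights(int no, int ni, std::vector<int>& i0,
                           std::vector<int>& i1, std::vector<double>& w1) {
  const double scale = (double)ni / no;
  i0.resize(no); i1.resize(no); w1.resize(no);
  for (int o = 0; o < no; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > ni - 1) s = ni - 1;
    int a = (int)std::floor(s);
    if (a > ni - 1) a = ni - 1;
    int b = a + 1 < ni ? a + 1 : ni - 1;
    i0[o] = a; i1[o] = b; w1[o] = s - a;
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = dims4(x, "input");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> wr, wc;
  resize_weights(Ho, H, r0, r1, wr);
  resize_weights(Wo, W, c0, c1, wc);
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* s = xp + ((size_t)n * C + c) * H * W;
      double* d = yp + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double v00 = s[(size_t)c0[j] * H + r0[i]];
          const double v10 = s[(size_t)c0[j] * H + r1[i]];
          const double v01 = s[(size_t)c1[j] * H + r0[i]];
          const double v11 = s[(size_t)c1[j] * H + r1[i]];
          const double a = wr[i], b = wc[j];
          d[(size_t)j * Ho + i] = (1 - a) * (1 - b) * v00 + a * (1 - b) * v10 +
                                  (1 - a) * b * v01 + a * b * v11;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_bilinear_bwd(NumericVector dy, int Hi, int Wi) {
  IntegerVector yd = dims4(dy, "gradient");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  std::vector<int> r0, r1, c0, c1;
  std::vector<double> wr, wc;
  resize_weights(Ho, Hi, r0, r1, wr);
  resize_weights(Wo, Wi, c0, c1, wc);
  NumericVector dx((size_t)Hi * Wi * C * N);
  dx.attr("dim") = IntegerVector::create(Hi, Wi, C, N);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* s = dxp + ((size_t)n * C + c) * Hi * Wi;
      const double* d = dyp + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const double g = d[(size_t)j * Ho + i];
          const double a = wr[i], b = wc[j];
          s[(size_t)c0[j] * Hi + r0[i]] += (1 - a) * (1 - b) * g;
          s[(size_t)c0[j] * Hi + r1[i]] += a * (1 - b) * g;
          s[(size_t)c1[j] * Hi + r0[i]] += (1 - a) * b * g;
          s[(size_t)c1[j] * Hi + r1[i]] += a * b * g;
        }
    }
  return dx;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), anisotropic spacing, by
// separable lower-envelope-of-parabolas passes.  Used by the ASSD fast path;
// correctness is pinned to the all-pairs oracle in the tests.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, double s2, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = s2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f = d;
}

// [[Rcpp::export]]
NumericMatrix cpp_edt_sq(LogicalMatrix feature, double sr, double sc) {
  const int H = feature.nrow(), W = feature.ncol();
  const double INF = 1e30;
  NumericMatrix D(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      D(i, j) = feature(i, j) ? 0.0 : INF;
  std::vector<double> buf;
  // pass along rows (row index varies, spacing sr)
  buf.resize(H);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) buf[i] = D(i, j);
    dt1d(buf, sr * sr, H);
    for (int i = 0; i < H; ++i) D(i, j) = buf[i];
  }
  // pass along columns (column index varies, spacing sc)
  buf.resize(W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) buf[j] = D(i, j);
    dt1d(buf, sc * sc, W);
    for (int j = 0; j < W; ++j) D(i, j) = buf[j];
  }
  return D;
}
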