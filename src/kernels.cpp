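// Dense tensor kernels for the saliency network.
// Layout convention: activation arrays are column-major (H, W, C, N);
// convolution weights are (KH, KW, Cin, Cout). im2col rows are ordered
// kh-fastest, then kw, then cin, matching the flattened weight array.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline NumericVector num4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector int4d(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void im2col_one(const double* x, int H, int W, int C,
                              int KH, int KW, int sh, int sw,
                              int ph, int pw, int dh, int dw,
                              int OH, int OW, arma::mat& cols) {
  // cols is (OH*OW) x (KH*KW*C); row p = oh + OH*ow, column r ordered
  // kh-fastest then kw then c, matching the flattened weight array.
  size_t P = (size_t)OH * OW;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        size_t r = kh + (size_t)KH * (kw + KW * c);
        double* dst = cols.memptr() + P * r;
        for (int ow = 0; ow < OW; ++ow) {
          int wy = ow * sw - pw + kw * dw;
          double* d2 = dst + (size_t)OH * ow;
          if (wy < 0 || wy >= W) {
            for (int oh = 0; oh < OH; ++oh) d2[oh] = 0.0;
            continue;
          }
          const double* xcol = xc + (size_t)H * wy;
          for (int oh = 0; oh < OH; ++oh) {
            int hy = oh * sh - ph + kh * dh;
            d2[oh] = (hy >= 0 && hy < H) ? xcol[hy] : 0.0;
          }
        }
      }
    }
  }
}

static inline void col2im_one(const arma::mat& cols, int H, int W, int C,
                              int KH, int KW, int sh, int sw,
                              int ph, int pw, int dh, int dw,
                              int OH, int OW, double* gx) {
  // cols is (OH*OW) x (KH*KW*C), as in im2col_one
  size_t P = (size_t)OH * OW;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int kw = 0; kw < KW; ++kw) {
      for (int kh = 0; kh < KH; ++kh) {
        size_t r = kh + (size_t)KH * (kw + KW * c);
        const double* src = cols.memptr() + P * r;
        for (int ow = 0; ow < OW; ++ow) {
          int wy = ow * sw - pw + kw * dw;
          if (wy < 0 || wy >= W) continue;
          const double* s2 = src + (size_t)OH * ow;
          double* gcol = gc + (size_t)H * wy;
          for (int oh = 0; oh < OH; ++oh) {
            int hy = oh * sh - ph + kh * dh;
            if (hy >= 0 && hy < H) gcol[hy] += s2[oh];
          }
        }
      }
    }
  }
}

static void conv_dims(const IntegerVector& xd, const IntegerVector& wd,
                      int sh, int sw, int ph, int pw, int dh, int dw,
                      int& H, int& W, int& C, int& N, int& KH, int& KW,
                      int& Cout, int& OH, int& OW) {
  H = xd[0]; W = xd[1]; C = xd[2]; N = xd[3];
  KH = wd[0]; KW = wd[1]; Cout = wd[3];
  if (wd[2] != C) stop("conv: channel mismatch");
  OH = (H + 2 * ph - dh * (KH - 1) - 1) / sh + 1;
  OW = (W + 2 * pw - dw * (KW - 1) - 1) / sw + 1;
  if (OH < 1 || OW < 1) stop("conv: output size < 1");
}

// [[Rcpp::export]]
NumericVector cppConvForward(NumericVector x, NumericVector w,
                             int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H, W, C, N, KH, KW, Cout, OH, OW;
  conv_dims(xd, wd, sh, sw, ph, pw, dh, dw, H, W, C, N, KH, KW, Cout, OH, OW);
  int K = KH * KW * C, P = OH * OW;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector y = num4d(OH, OW, Cout, N);
  arma::mat cols(P, K);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW,
               sh, sw, ph, pw, dh, dw, OH, OW, cols);
    arma::mat out(y.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    out = cols * Wm;
  }
  return y;
}

// [[Rcpp::export]]
List cppConvBackward(NumericVector x, NumericVector w, NumericVector gy,
                     int sh, int sw, int ph, int pw, int dh, int dw) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H, W, C, N, KH, KW, Cout, OH, OW;
  conv_dims(xd, wd, sh, sw, ph, pw, dh, dw, H, W, C, N, KH, KW, Cout, OH, OW);
  int K = KH * KW * C, P = OH * OW;
  arma::mat Wm(w.begin(), K, Cout, false, true);
  NumericVector gx = num4d(H, W, C, N);
  NumericVector gw = num4d(KH, KW, C, Cout);
  arma::mat Gw(gw.begin(), K, Cout, false, true);
  arma::mat cols(P, K), gcols(P, K);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C, KH, KW,
               sh, sw, ph, pw, dh, dw, OH, OW, cols);
    arma::mat G((double*)gy.begin() + (size_t)P * Cout * n, P, Cout, false, true);
    Gw += cols.t() * G;
    gcols = G * Wm.t();
    col2im_one(gcols, H, W, C, KH, KW, sh, sw, ph, pw, dh, dw, OH, OW,
               gx.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// Bilinear resize, align_corners = FALSE (half-pixel centers).
// [[Rcpp::export]]
NumericVector cppBilinearForward(NumericVector x, int OH, int OW) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = num4d(OH, OW, C, N);
  double rh = (double)H / OH, rw = (double)W / OW;
  std::vector<int> h0(OH), h1(OH); std::vector<double> lh(OH);
  for (int i = 0; i < OH; ++i) {
    double s = (i + 0.5) * rh - 0.5;
    if (s < 0) s = 0; if (s > H - 1) s = H - 1;
    h0[i] = (int)std::floor(s); h1[i] = std::min(h0[i] + 1, H - 1); lh[i] = s - h0[i];
  }
  std::vector<int> w0(OW), w1(OW); std::vector<double> lw(OW);
  for (int j = 0; j < OW; ++j) {
    double s = (j + 0.5) * rw - 0.5;
    if (s < 0) s = 0; if (s > W - 1) s = W - 1;
    w0[j] = (int)std::floor(s); w1[j] = std::min(w0[j] + 1, W - 1); lw[j] = s - w0[j];
  }
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)OH * OW * cn;
    for (int j = 0; j < OW; ++j) {
      const double* c0 = xs + (size_t)H * w0[j];
      const double* c1 = xs + (size_t)H * w1[j];
      double b = lw[j];
      for (int i = 0; i < OH; ++i) {
        double a = lh[i];
        double top = c0[h0[i]] * (1 - a) + c0[h1[i]] * a;
        double bot = c1[h0[i]] * (1 - a) + c1[h1[i]] * a;
        ys[i + (size_t)OH * j] = top * (1 - b) + bot * b;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cppBilinearBackward(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int OH = gd[0], OW = gd[1], C = gd[2], N = gd[3];
  NumericVector gx = num4d(H, W, C, N);
  double rh = (double)H / OH, rw = (double)W / OW;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* gs = gy.begin() + (size_t)OH * OW * cn;
    double* xs = gx.begin() + (size_t)H * W * cn;
    for (int j = 0; j < OW; ++j) {
      double s = (j + 0.5) * rw - 0.5;
      if (s < 0) s = 0; if (s > W - 1) s = W - 1;
      int w0 = (int)std::floor(s), w1 = std::min(w0 + 1, W - 1);
      double b = s - w0;
      for (int i = 0; i < OH; ++i) {
        double t = (i + 0.5) * rh - 0.5;
        if (t < 0) t = 0; if (t > H - 1) t = H - 1;
        int h0 = (int)std::floor(t), h1 = std::min(h0 + 1, H - 1);
        double a = t - h0, g = gs[i + (size_t)OH * j];
        xs[h0 + (size_t)H * w0] += g * (1 - a) * (1 - b);
        xs[h1 + (size_t)H * w0] += g * a * (1 - b);
        xs[h0 + (size_t)H * w1] += g * (1 - a) * b;
        xs[h1 + (size_t)H * w1] += g * b * a;
      }
    }
  }
  return gx;
}

// 2x2 max pooling, stride 2 (even H, W assumed by caller).
// [[Rcpp::export]]
List cppMaxPool2Forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int OH = H / 2, OW = W / 2;
  NumericVector y = num4d(OH, OW, C, N);
  IntegerVector idx = int4d(OH, OW, C, N); // flat index into (H,W) plane
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)OH * OW * cn;
    int* is = idx.begin() + (size_t)OH * OW * cn;
    for (int j = 0; j < OW; ++j) {
      for (int i = 0; i < OH; ++i) {
        int best = 2 * i + H * (2 * j);
        double bv = xs[best];
        int cand[3] = {2 * i + 1 + H * (2 * j), 2 * i + H * (2 * j + 1),
                       2 * i + 1 + H * (2 * j + 1)};
        for (int k = 0; k < 3; ++k)
          if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
        ys[i + (size_t)OH * j] = bv;
        is[i + (size_t)OH * j] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cppMaxPool2Backward(NumericVector gy, IntegerVector idx, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int OH = gd[0], OW = gd[1], C = gd[2], N = gd[3];
  NumericVector gx = num4d(H, W, C, N);
  size_t plane = (size_t)OH * OW;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* gs = gy.begin() + plane * cn;
    const int* is = idx.begin() + plane * cn;
    double* xs = gx.begin() + (size_t)H * W * cn;
    for (size_t p = 0; p < plane; ++p) xs[is[p]] += gs[p];
  }
  return gx;
}

// Adaptive average pooling to (OH, OW) with floor/ceil bin edges.
// [[Rcpp::export]]
NumericVector cppAdaptiveAvgForward(NumericVector x, int OH, int OW) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = num4d(OH, OW, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (size_t)H * W * cn;
    double* ys = y.begin() + (size_t)OH * OW * cn;
    for (int j = 0; j < OW; ++j) {
      int w0 = (j * W) / OW, w1 = ((j + 1) * W + OW - 1) / OW;
      for (int i = 0; i < OH; ++i) {
        int h0 = (i * H) / OH, h1 = ((i + 1) * H + OH - 1) / OH;
        double s = 0;
        for (int wv = w0; wv < w1; ++wv)
          for (int hv = h0; hv < h1; ++hv) s += xs[hv + (size_t)H * wv];
        ys[i + (size_t)OH * j] = s / ((h1 - h0) * (w1 - w0));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cppAdaptiveAvgBackward(NumericVector gy, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int OH = gd[0], OW = gd[1], C = gd[2], N = gd[3];
  NumericVector gx = num4d(H, W, C, N);
  for (int cn = 0; cn < C * N; ++cn) {
    const double* gs = gy.begin() + (size_t)OH * OW * cn;
    double* xs = gx.begin() + (size_t)H * W * cn;
    for (int j = 0; j < OW; ++j) {
      int w0 = (j * W) / OW, w1 = ((j + 1) * W + OW - 1) / OW;
      for (int i = 0; i < OH; ++i) {
        int h0 = (i * H) / OH, h1 = ((i + 1) * H + OH - 1) / OH;
        double g = gs[i + (size_t)OH * j] / ((h1 - h0) * (w1 - w0));
        for (int wv = w0; wv < w1; ++wv)
          for (int hv = h0; hv < h1; ++hv) xs[hv + (size_t)H * wv] += g;
      }
    }
  }
  return gx;
}

// Batch normalization over (H, W, N) per channel, training statistics.
// [[Rcpp::export]]
List cppBnForward(NumericVector x, NumericVector gamma, NumericVector beta,
                  double eps) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector y = num4d(H, W, C, N), mean(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + plane * (c + (size_t)C * n);
      for (size_t p = 0; p < plane; ++p) { s += xs[p]; s2 += xs[p] * xs[p]; }
    }
    double m = s / (plane * N);
    double v = s2 / (plane * N) - m * m;
    if (v < 0) v = 0;
    double is = 1.0 / std::sqrt(v + eps);
    mean[c] = m; invstd[c] = is;
    double g = gamma[c], b = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + plane * (c + (size_t)C * n);
      double* ys = y.begin() + plane * (c + (size_t)C * n);
      for (size_t p = 0; p < plane; ++p) ys[p] = g * (xs[p] - m) * is + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cppBnBackward(NumericVector x, NumericVector gamma, NumericVector mean,
                   NumericVector invstd, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  double M = (double)plane * N;
  NumericVector gx = num4d(H, W, C, N), ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    double m = mean[c], is = invstd[c], g = gamma[c];
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + plane * (c + (size_t)C * n);
      const double* gs = gy.begin() + plane * (c + (size_t)C * n);
      for (size_t p = 0; p < plane; ++p) {
        sg += gs[p];
        sgx += gs[p] * (xs[p] - m) * is;
      }
    }
    ggamma[c] = sgx; gbeta[c] = sg;
    for (int n = 0; n < N; ++n) {
      const double* xs = x.begin() + plane * (c + (size_t)C * n);
      const double* gs = gy.begin() + plane * (c + (size_t)C * n);
      double* os = gx.begin() + plane * (c + (size_t)C * n);
      for (size_t p = 0; p < plane; ++p) {
        double xh = (xs[p] - m) * is;
        os[p] = g * is * (gs[p] - sg / M - xh * sgx / M);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// Per-pixel mean and max over channels (squeeze for spatial attention).
// [[Rcpp::export]]
List cppChannelReduce(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t plane = (size_t)H * W;
  NumericVector mn = num4d(H, W, 1, N), mx = num4d(H, W, 1, N);
  IntegerVector amx = int4d(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    for (size_t p = 0; p < plane; ++p) {
      double s = 0, best = -INFINITY; int bi = 0;
      for (int c = 0; c < C; ++c) {
        double v = x[p + plane * (c + (size_t)C * n)];
        s += v;
        if (v > best) { best = v; bi = c; }
      }
      mn[p + plane * n] = s / C;
      mx[p + plane * n] = best;
      amx[p + plane * n] = bi;
    }
  }
  return List::create(_["mean"] = mn, _["max"] = mx, _["argmax"] = amx);
}

// Scatter gradients of the channel mean/max squeeze back to (H,W,C,N).
// [[Rcpp::export]]
NumericVector cppChannelReduceBackward(NumericVector gmean, NumericVector gmax,
                                       IntegerVector amx, int C) {
  IntegerVector gd = gmean.attr("dim");
  int H = gd[0], W = gd[1], N = gd[3];
  size_t plane = (size_t)H * W;
  NumericVector gx = num4d(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (size_t p = 0; p < plane; ++p) {
      double gm = gmean[p + plane * n] / C;
      for (int c = 0; c < C; ++c) gx[p + plane * (c + (size_t)C * n)] += gm;
      gx[p + plane * ((size_t)amx[p + plane * n] + (size_t)C * n)] +=
        gmax[p + plane * n];
    }
  }
  return gx;
}

// Plain 2-D correlation with zero padding ("same" size), metric helper.
// [[Rcpp::export]]
NumericMatrix cppFilter2Zero(NumericMatrix x, NumericMatrix k) {
  int H = x.nrow(), W = x.ncol(), KH = k.nrow(), KW = k.ncol();
  int ch = KH / 2, cw = KW / 2;
  NumericMatrix y(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0;
      for (int b = 0; b < KW; ++b) {
        int wj = j + b - cw;
        if (wj < 0 || wj >= W) continue;
        for (int a = 0; a < KH; ++a) {
          int wi = i + a - ch;
          if (wi < 0 || wi >= H) continue;
          s += x(wi, wj) * k(a, b);
        }
      }
      y(i, j) = s;
    }
  return y;
}

// Exact Euclidean distance transform to the nearest TRUE pixel, with the
// 1-based flat index of that pixel (Felzenszwalb-Huttenlocher envelopes).
// [[Rcpp::export]]
List cppDistanceTransform(LogicalMatrix fg) {
  int H = fg.nrow(), W = fg.ncol();
  // BIG is a finite sentinel for "no foreground in this column": far larger
  // than any attainable squared image distance, yet safe in the envelope
  // arithmetic (true INF would yield INF-INF = NaN intersections).
  const double BIG = 1e9, INF = 1e18;
  NumericMatrix d2(H, W);
  IntegerMatrix nearestRow(H, W), idx(H, W);
  // pass 1: per column, distance (in rows) to nearest fg pixel in that column
  for (int j = 0; j < W; ++j) {
    std::vector<double> g(H, INF);
    std::vector<int> src(H, -1);
    for (int i = 0; i < H; ++i) if (fg(i, j)) { g[i] = 0; src[i] = i; }
    for (int i = 1; i < H; ++i)
      if (g[i - 1] + 1 < g[i]) { g[i] = g[i - 1] + 1; src[i] = src[i - 1]; }
    for (int i = H - 2; i >= 0; --i)
      if (g[i + 1] + 1 < g[i]) { g[i] = g[i + 1] + 1; src[i] = src[i + 1]; }
    for (int i = 0; i < H; ++i) {
      d2(i, j) = (src[i] < 0) ? BIG : g[i] * g[i];
      nearestRow(i, j) = src[i];
    }
  }
  // pass 2: per row, lower envelope of parabolas over columns
  std::vector<int> v(W); std::vector<double> z(W + 1);
  for (int i = 0; i < H; ++i) {
    int k = 0; v[0] = 0; z[0] = -INF; z[1] = INF;
    for (int q = 1; q < W; ++q) {
      double fq = d2(i, q);
      double s;
      while (true) {
        double fv = d2(i, v[k]);
        s = ((fq + (double)q * q) - (fv + (double)v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
        if (s <= z[k]) { --k; } else break;
      }
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
    k = 0;
    std::vector<double> out(W); std::vector<int> srcCol(W);
    for (int q = 0; q < W; ++q) {
      while (z[k + 1] < q) ++k;
      double dq = (double)(q - v[k]) * (q - v[k]) + d2(i, v[k]);
      out[q] = dq; srcCol[q] = v[k];
    }
    for (int q = 0; q < W; ++q) {
      d2(i, q) = out[q];
      int sc = srcCol[q];
      int sr = nearestRow(i, sc);
      idx(i, q) = (sr < 0) ? NA_INTEGER : (sr + 1 + H * sc); // 1-based flat
    }
  }
  NumericMatrix dist(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      dist(i, j) = (d2(i, j) >= BIG / 2) ? R_PosInf : std::sqrt(d2(i, j));
  return List::create(_["dist"] = dist, _["index"] = idx);
}
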